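Package: mgsr
Title: Multi-Granular Stacked Regression for Emergency Department Demand
Version: 0.1.0
Authors@R:
    person("Regional", "Forecasting Group", email = "mgsr@example.org",
           role = c("aut", "cre"))
Description: Tools for forecasting long-term emergency department (ED)
    demand across commissioning regions from multi-source, multi-resolution
    public health-service data. Curates monthly service-capacity records and
    annual population-health records into a single regional panel, fits a
    multi-granular stacked regression (MGSR): two level-0 random-forest
    models at monthly and annual granularity combined by a level-1 ordinary
    least squares regression. Includes a seeded synthetic-data generator,
    repeated k-fold cross-validation, permutation variable importance, and
    policy scenario ("what-if") projection of future demand.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
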