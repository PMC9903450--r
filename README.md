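# mgsr

Forecasting long-term emergency department (ED) demand across regional
commissioning units (historically CCGs, now sub-ICBs) from public
multi-source data. Attendances respond both to the capacity of
neighbouring urgent-care services — GP appointments, 111 calls offered,
ambulance calls answered — which varies **monthly**, and to population
size, age structure and population health (the ONS Health Index domains
*People*, *Places*, *Lives*), which change **annually**. A single model
at one temporal resolution wastes one of the two signals.

`mgsr` implements a **multi-granular stacked regression**: two level-0
random-forest regressors fit at their natural granularity, combined by a
level-1 ordinary-least-squares regression,

```
ŷ(r, m) = β₀ + β_c · ĉ(r, m) + β_h · ĥ(r, year(m))
```

where `ĉ` is the monthly capacity-model prediction from
(GP, 111, ambulance) rates per 10,000 people, and `ĥ` is the annual
population-health prediction from (population/10⁴, %>65, People,
Places, Lives), broadcast to every month of the region-year. Level-0
models are fit on 70% of the rows, the combiner on a disjoint 10%, and
performance is reported on the held-out 20%, repeated so that every
row is validated exactly once per repeat (5 repeats × 5 folds = 25
validation sets).

The package also provides:

* **Curation** of raw multi-source records: provider→region
  aggregation, population-share apportionment of contract-level counts,
  merger-group aggregation (counts summed, indices population-weighted),
  per-10,000 scaling, and missing-record removal with full accounting.
* A seeded **synthetic-data generator** whose marginals emulate the
  published cohort statistics, with a documented capacity signal,
  health signal, winter-peaking seasonality and Gaussian noise, so the
  whole pipeline is testable without any download.
* **Evaluation**: R², MAPE, year-ahead forecast accuracy with winter
  (Dec–Feb) error, per-model Gini importance and stack-wide
  validation-set permutation importance.
* **Scenario projection** over a multi-year horizon: do-nothing
  (population evolves, everything else frozen), ±capacity uplifts, and
  a health-equity ramp raising below-average Health-Index values by
  0.2 points/year up to the baseline average, with 4-month rolling
  average series.

## Worked example

```r
library(mgsr)

sim <- simulate_mgsr_data(generator_config(n_regions = 76, n_months = 24,
                                           seed = 42))
cur <- curate(sim$raw)
print(cur$log)
#> Curation log
#>   regions: 76 initial, 0 dropped (incomplete ED data)
#>   potential records: 1824
#>   final records: 1824

report <- cross_validate(cur$panel, n_repeats = 2, n_folds = 5, seed = 42)
print(report)
#> Repeated 2 x 5-fold cross-validation (10 validation sets)
#>   MGSR      R2 = 0.932 +/- 0.005  (pooled 0.932)
#>   capacity  R2 = 0.539
#>   health    R2 = 0.921
#>   MAPE = 4.8%

model <- fit_mgsr(cur$panel, split = NULL, seed = 42)
print(model)
#> Multi-granular stacked regression
#>   combiner: y = -76.674 + 0.634 * capacity + 0.498 * health
```

The cross-validation report shows the stacking gain: the combined model
explains more held-out variance (0.932) than the capacity model (0.539)
or the population-health model (0.921) alone, mirroring the behaviour
the architecture was designed for. The combiner coefficients weight the
two level-0 predictions; MAPE is the mean absolute percentage error of
monthly predictions on validation rows.

`curate()` accepts either a directory of CSVs (`providers.csv`,
`contracts.csv`, `contract_map.csv`, `regions.csv`, `gp.csv`; UTF-8,
header row, months as `YYYY-MM`) or the equivalent data frames. See
`?curate`, `?cross_validate`, `?forecast_scenario`.

## Command line

A thin CLI wraps the pipeline (`inst/cli/mgsr`, installed under
`system.file("cli", "mgsr", package = "mgsr")`):

```sh
mgsr simulate --config config.yaml --out raw/
mgsr curate   --raw raw/ --out artifacts/
mgsr fit      --panel artifacts/panel.csv --out model.json
mgsr evaluate --panel artifacts/panel.csv --report report.json
mgsr forecast --model model.json --panel artifacts/panel.csv \
              --projections projections.csv --scenario health_ramp --out series.csv
mgsr run      --config config.yaml --out artifacts/   # end to end + manifest
```

Configuration is a single YAML file (seeds, generator settings,
hyper-parameters, CV design, scenario defaults); unknown keys are
rejected, flags override the file, and `run` writes a manifest with a
config hash and every seed used so runs are bit-reproducible.

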