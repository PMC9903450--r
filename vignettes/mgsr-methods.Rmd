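---
title: "Methods: the multi-granular stacked regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-granular stacked regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its model, its data
conventions, the synthetic world used to test it, and the design
decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

Monthly ED attendances per region respond to two kinds of covariates
that live at different temporal resolutions. Service-capacity rates
(GP appointments, 111 calls offered, ambulance calls answered, all per
10,000 people) vary month to month; population, age structure and the
three ONS Health-Index domains (People, Places, Lives; base 100, values
above 100 healthier than the 2015 reference) change once a year. A
single regressor at monthly resolution treats the annual block as
quasi-constant clutter; one at annual resolution discards the monthly
signal. The stacked architecture keeps both:

* **Capacity model** — a random-forest regressor of the monthly
  attendance rate on the three capacity rates.
* **Population-health model** — a random-forest regressor of the
  *annual mean* of the monthly attendance rate on the five annual
  covariates, fit on one row per region-year.
* **Combiner** — an ordinary-least-squares regression, with intercept,
  of the monthly attendance rate on the two level-0 predictions. The
  health prediction is constant across the months of a region-year
  (its covariates are), i.e. the annual prediction is broadcast.

The combiner includes an intercept. This is plain least-squares
practice, and an unconstrained combiner is also what the published
coefficients of the architecture this package implements imply (their
sum is visibly not 1). With an intercept, the stacked fit can never
have larger residual sum of squares on its training rows than either
level-0 prediction alone; the test suite asserts exactly that.

### Data splitting

Each cross-validation repeat shuffles the panel rows and cuts five
folds. For a fold: the held-out fold (20%) is validation; the
remaining 80% is split 7/8 : 1/8, giving level-0 rows (70% of all
data) and combiner rows (10%). Level-0 models never see combiner or
validation rows; the health model's annual targets are computed from
level-0 rows only, so a partially covered region-year uses the mean of
its available months. Splitting is over rows (region-months), not
regions; months of one region can therefore appear on both sides of a
split. That is the protocol this architecture is evaluated with in the
literature it comes from, and the leakage it implies across months of
one region is documented rather than corrected.

For forecasting, the model is refit with every stage on the full panel
(`fit_mgsr(panel, split = NULL)`): level-0 models and combiner all see
all rows. This maximizes the data behind the deployed model at the
price of an optimistic in-sample combiner; all reported accuracy comes
from the cross-validation protocol, never from this refit.

### The forest

No random-forest implementation is available in the target
environment, so the package carries its own: bagged CART regression
trees, variance-reduction splits, a random feature subset per split,
and impurity-decrease (Gini-type) importances normalized to sum to 1.
Two properties matter for the package contracts:

* Predictions are means of training responses, hence always inside the
  training-target range — the model cannot extrapolate. The scenario
  machinery inherits this bound.
* Fits are driven by a private mt19937 stream (no R RNG, no standard
  library distribution adapters whose output is implementation
  defined), so a seed produces the identical forest on every platform.

Level-0 models try **all** features at every split (`mtry = p`). This
is the regression default of the reference toolchain the architecture
was originally built with, and at 3–5 predictors per model the usual
`p/3` heuristic only adds variance. Default hyper-parameters are 200
trees, unbounded depth, minimum split size 2. The tuning grid is
`n_trees ∈ {50, 100, 200, 500} × max_depth ∈ {2, 4, 8, unbounded}`;
"maximise validation performance while minimising complexity" is
operationalized as the one-standard-deviation rule (among grid points
within one sd of the best mean validation R², pick fewest trees, then
shallowest; identical per-fold fit seeds across grid points make
behaviourally identical settings tie exactly). Tuning is per model and
optional (`cross_validate(..., tune = TRUE)` re-selects once per
repeat); the default evaluation uses the fixed defaults.

## Curation rules

One observation per region per month, built as:

1. **Aggregation**: provider-level ED counts are summed over the
   providers mapped to a region.
2. **Stratification**: contract-level 111/ambulance counts are
   apportioned to member regions proportionally to population in the
   calendar year of the record; allocations conserve the contract total
   to 1e-9 relative.
3. **Merger aggregation**: regions that merged are combined before
   scaling — counts and populations summed; unit-free indices
   (People/Places/Lives) as population-weighted means, because summing
   a base-100 index is meaningless.
4. **Region removal**: regions with incomplete ED attendance series
   never enter the panel; potential records = retained regions ×
   months.
5. **Scaling**: counts per 10,000 people; population divided by
   10,000; %>65 = 100 × over-65 / population.
6. **Missing-record removal**: a row survives only if every field is
   present. A row missing several variables is counted once, under the
   first missing group in the fixed order *health indices, 111,
   ambulance, GP, attendances, population*; the log's counts are
   therefore disjoint and sum to the rows removed.

Months are ISO `YYYY-MM` labels; internally a 0-based index orders
them. No calendar variable is ever a model predictor.

## The synthetic world

`simulate_mgsr_data()` emits raw files in the curation schema plus a
row-aligned ground truth. Defaults state the world once:

* 76 regions × 24 months (two calendar years from 2018-01).
* Populations log-normal, median ≈ 500k, clipped to [1e5, 3.4e6];
  %>65 ~ N(19, 4); People ~ N(99, 6), Places ~ N(100, 2),
  Lives ~ N(100, 6), constant within a region-year, drifting slowly
  between years (populations ≈ +0.7%/yr) unless `annual_drift = FALSE`.
* Capacity rates are region-level log-normal bases times small monthly
  log-normal innovations, mean-corrected so the marginal means hit the
  configured targets (GP 4382, 111 354, ambulance 352 per 10,000 — the
  published cohort means).
* 111 contracts group 8 regions, ambulance contracts ≈ 11 groups,
  mirroring the real contract geography; the covariates downstream
  models see are the *post-stratification* rates, recomputed with the
  curation operation itself, so generation and curation agree exactly.

The latent attendance rate is
`y = w_h·f_h + w_c·f_c + seasonal + ε`, `ε ~ N(0, σ²)`, σ = 25 by
default, with fixed documented forms (linear terms plus one saturating
term each):

```
f_c = 0.04·gp + 0.18·c111 + 0.28·amb + 40·tanh((amb − 350)/300)
f_h = 2.0·pop + 4.0·pct65 + 0.8·(100 − people) + 0.5·(100 − places)
      + 1.6·(100 − lives) + 30·tanh((pop − 60)/50)
```

so attendances *fall* as health indices rise (the health-ramp scenario
has a known monotone effect to recover), population is the dominant
single driver (what the permutation-importance tests must find), and
ambulance carries most of the capacity variance. Seasonality is a
sinusoid peaking in January (amplitude 15 per 10,000 by default), so
December–February sit near the maximum; it is invisible to the models
(no calendar predictors) and acts as structured nuisance. One seed
drives a hierarchical generator — region draws first, then one
4-draws-per-month stream per region — so extending the window neither
reshuffles regions nor earlier months.

Missingness injection blanks exactly the requested number of panel
rows per variable at each variable's native granularity (region-years
for the health index, contract-months for 111/ambulance, region-months
otherwise) and errors if a count is not representable. The
study-shaped fixture (`paper_shaped_fixture()`) uses this machinery to
reproduce the published curation accounting exactly: 81 regions of
which 5 have incomplete ED data, 48 health-index rows missing (two
retained regions, both years — which also makes the final panel
represent 74 regions), 158 disjoint 111 rows missing (a 7-region
contract × 22 months plus a 1-region contract × 4 months).

What a green test on this world does **not** establish: performance on
the real curated data (different dependence structure, outlier regions,
operational shocks), spatial correlation between regions, or calendar
effects beyond a smooth sinusoid. The published real-data headline
metrics are deliberately not targets of any test here.

## Evaluation and importance

R² is `1 − SS_res/SS_tot` (undefined and an error for constant truth);
MAPE is the mean of `|truth − prediction|/truth`, a fraction
internally, percent in printed output. `cross_validate()` reports the
per-fold mean ± sd and also a pooled R² (predictions of all rows
assembled from their validation folds, averaged over repeats), since
display conventions in this literature pool predictions.
`forecast_accuracy()` trains on one calendar year, forecasts the next,
and scores the across-region monthly-mean series: MAPE over months,
per-month signed errors, and the December–February mean absolute error
("winter error").

Permutation importance holds the fitted stack fixed and permutes one
covariate within the validation rows; annual covariates are permuted
at region-year level and then broadcast, so the permuted column is
still annual. PI = R²(unpermuted) − R²(permuted), averaged over 5 × 5
folds. Two numerical facts are asserted by tests and worth knowing: a
constant column has PI exactly 0 (permutation is a no-op), and PI has
**no upper cap at the unpermuted R²** — R² is unbounded below, so
permuting a dominant covariate can push the permuted R² far below zero
and PI above 1.

## Scenarios

`build_future_panel()` copies the baseline year month-for-month into
each horizon year and substitutes only projected population and %>65;
capacity rates (per 10,000) and health indices stay at baseline. The
frozen per-capita rates are a modelling convention inherited from the
do-nothing construction: as population grows, implied raw capacity
grows with it, and this is deliberate and documented rather than
corrected. Transformations:

* `uplift_gp` / `uplift_111` / `uplift_ambulance`: the named rate ×
  (1 + fraction), default +10%, immediately and in every future month.
* `health_ramp`: for each region and each index below the baseline
  cross-region average (unweighted mean over regions — the natural
  reading of "baseline average"), value(year k) =
  min(baseline + 0.2·k, average).
* Projections step yearly (no monthly interpolation): the quantities
  being projected are annual by nature.

Forecast series average the model's monthly predictions across regions
and append them to the baseline year's observed means; the plotted
convention is a trailing 4-month rolling mean (the current month and
three prior).

## Numerical choices and edge cases

* Split thresholds are midpoints between adjacent distinct values;
  when two values are so close that the midpoint rounds up to the
  upper value, the lower value is used, which keeps the partition
  non-degenerate (this matters because population-share stratification
  gives contract members per-capita rates identical up to float
  rounding).
* A constant-target forest has no splits; its importance vector is
  reported uniform so it still sums to 1.
* Collinear level-0 predictions make the OLS system rank-deficient;
  the aliased coefficient is set to 0 rather than NA.
* Curation is pure data-frame arithmetic with a deterministic ordering
  throughout: identical inputs give identical output bytes.
* All seeds are explicit; seeds derived internally stay below 2^31.

## Known limitations

* The forest cannot predict outside the training-target range, so the
  stack under-predicts in regions far outside the training
  distribution — inherited from the architecture, visible in scenario
  forecasts as saturation.
* Row-wise splitting leaks month-to-month information within a region
  into validation scores (documented above).
* The health model sees at most one row per region-year; with two
  years of data its training sets are small and its fold-to-fold
  variance is large — the same small-sample behaviour the original
  analysis reports.
* Scenario effects are aggregate: region-level responses to a
  transformation can differ in sign from the across-region mean.
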