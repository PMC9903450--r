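#' Scenario specification
#'
#' The five policy scenarios: `do_nothing` (only population and % over
#' 65 evolve), a 10% immediate uplift of one service's capacity
#' (`uplift_111`, `uplift_gp`, `uplift_ambulance`), and `health_ramp`
#' (below-average People/Places/Lives values rise 0.2 points per year
#' until they reach the baseline average).
#'
#' @param name One of `do_nothing`, `uplift_111`, `uplift_gp`,
#'   `uplift_ambulance`, `health_ramp`.
#' @param uplift_fraction Capacity uplift as a fraction (default 0.10).
#' @param ramp_step Health-Index points gained per year (default 0.2).
#' @param horizon_years Forecast horizon (default 4 years).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name = c("do_nothing", "uplift_111", "uplift_gp",
                                   "uplift_ambulance", "health_ramp"),
                          uplift_fraction = 0.10, ramp_step = 0.2,
                          horizon_years = 4L) {
  name <- match.arg(name)
  stopifnot(uplift_fraction >= 0, ramp_step > 0, horizon_years >= 1)
  structure(list(name = name, uplift_fraction = uplift_fraction,
                 ramp_step = ramp_step,
                 horizon_years = as.integer(horizon_years)),
            class = "scenario_spec")
}

#' Build the future covariate panel for forecasting
#'
#' For each horizon year, covariates copy the baseline year month for
#' month; only population (scaled) and % over 65 are replaced with
#' projected values. Capacity rates and health indices stay at baseline
#' (the do-nothing construction); scenario transformations are applied
#' afterwards.
#'
#' @param baseline Curated panel rows of the baseline year (12 months
#'   per region).
#' @param projections Data frame `region_id`, `year`, `population`,
#'   `population_over_65` (persons) covering every horizon year for
#'   every baseline region.
#' @param horizon Number of future years.
#' @return Future panel rows: baseline columns plus `horizon_year`
#'   (1-based future year index), with shifted month labels.
#' @export
build_future_panel <- function(baseline, projections, horizon) {
  check_columns(baseline, c("region_id", "month", ALL_COVARIATES),
                "baseline panel")
  check_columns(projections,
                c("region_id", "year", "population", "population_over_65"),
                "projections")
  yrs <- unique(month_year(baseline$month))
  if (length(yrs) != 1) stop("baseline must cover exactly one calendar year")
  per_region <- table(baseline$region_id)
  if (any(per_region != 12)) {
    stop("baseline must have 12 months for every region")
  }
  out <- lapply(seq_len(horizon), function(k) {
    fut <- baseline
    fut$month <- month_shift(baseline$month, 12L * k)
    fut$horizon_year <- k
    key <- match(paste(fut$region_id, yrs + k),
                 paste(projections$region_id, projections$year))
    if (anyNA(key)) {
      miss <- unique(fut$region_id[is.na(key)])
      stop("missing projection for year ", yrs + k, ", region(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    fut$population_scaled <- projections$population[key] / 10000
    fut$pct_over_65 <- 100 * projections$population_over_65[key] /
      projections$population[key]
    fut
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Uplift one service's capacity
#'
#' Multiplies the named capacity rate by `1 + fraction` in every row;
#' all other columns are untouched.
#'
#' @param rows Panel rows (typically a future panel).
#' @param service One of `"gp"`, `"111"`, `"ambulance"`.
#' @param fraction Uplift fraction (0.10 = +10%).
#' @return The transformed rows.
#' @export
apply_uplift <- function(rows, service, fraction) {
  col <- switch(service,
                gp = "gp_capacity", "111" = "capacity_111",
                ambulance = "ambulance_capacity",
                stop("unknown service: ", service))
  check_columns(rows, col, "panel rows")
  rows[[col]] <- rows[[col]] * (1 + fraction)
  rows
}

#' Ramp below-average health indices toward the baseline average
#'
#' For each region and each of People/Places/Lives whose baseline value
#' is below the baseline (cross-region) average, the value in horizon
#' year k is `min(baseline_value + k * step, baseline_average)`. Regions
#' at or above the average are unchanged.
#'
#' @param rows Future panel rows carrying `horizon_year` and baseline
#'   index values.
#' @param baseline_averages Named vector with `people_index`,
#'   `places_index`, `lives_index`: unweighted means over the regions of
#'   the baseline year.
#' @param step Points gained per year.
#' @return The transformed rows.
#' @export
apply_health_ramp <- function(rows, baseline_averages, step) {
  check_columns(rows, c("horizon_year", "people_index", "places_index",
                        "lives_index"), "future panel")
  for (v in c("people_index", "places_index", "lives_index")) {
    avg <- baseline_averages[[v]]
    below <- rows[[v]] < avg
    rows[[v]][below] <- pmin(rows[[v]][below] +
                               rows$horizon_year[below] * step, avg)
  }
  rows
}

#' Trailing rolling mean
#'
#' @param series Numeric series (length >= `window`).
#' @param window Window size in months.
#' @return Series of length `length(series) - window + 1`: the mean of
#'   each window of `window` consecutive values ending at that point.
#' @export
rolling_mean <- function(series, window = 4L) {
  n <- length(series)
  if (n < window) stop("series shorter than the rolling window")
  vapply(window:n, function(i) mean(series[(i - window + 1):i]), 0.0)
}

#' Forecast mean monthly attendances under a scenario
#'
#' Builds the future panel from the baseline year and the population
#' projections, applies the scenario transformation, predicts monthly
#' rates with the fitted MGSR, averages across regions per month,
#' appends the series to the baseline year's observed means, and
#' computes a 4-month trailing rolling average.
#'
#' @param model A fitted `mgsr_model` (refit to the entire curated
#'   panel for forecasting use).
#' @param baseline Curated panel rows of the baseline year.
#' @param projections See [build_future_panel()].
#' @param spec A [scenario_spec()].
#' @return A `forecast_series`: `months` and `mean_attendances` for the
#'   forecast horizon, `baseline_months`/`baseline_series` (observed),
#'   `rolling` (over baseline + forecast), and the scenario name.
#' @export
forecast_scenario <- function(model, baseline, projections,
                              spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  future <- build_future_panel(baseline, projections, spec$horizon_years)
  future <- switch(
    spec$name,
    do_nothing = future,
    uplift_111 = apply_uplift(future, "111", spec$uplift_fraction),
    uplift_gp = apply_uplift(future, "gp", spec$uplift_fraction),
    uplift_ambulance = apply_uplift(future, "ambulance", spec$uplift_fraction),
    health_ramp = {
      base_year <- baseline[!duplicated(baseline$region_id), ]
      avgs <- vapply(c("people_index", "places_index", "lives_index"),
                     function(v) mean(base_year[[v]]), 0.0)
      apply_health_ramp(future, avgs, spec$ramp_step)
    })
  pred <- predict_mgsr(model, future)
  months <- sort(unique(future$month))
  series <- vapply(months, function(m) mean(pred[future$month == m]), 0.0)
  base_months <- sort(unique(baseline$month))
  base_series <- vapply(base_months, function(m) {
    mean(baseline[[TARGET_VAR]][baseline$month == m]) }, 0.0)
  structure(list(scenario = spec$name,
                 months = months,
                 mean_attendances = unname(series),
                 baseline_months = base_months,
                 baseline_series = unname(base_series),
                 rolling = rolling_mean(c(base_series, series), 4L),
                 spec = spec),
            class = "forecast_series")
}

#' @export
print.forecast_series <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d forecast months, mean %.1f (baseline %.1f)\n",
              x$scenario, length(x$months), mean(x$mean_attendances),
              mean(x$baseline_series)))
  invisible(x)
}
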