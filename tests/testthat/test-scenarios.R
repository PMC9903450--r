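panel_sc <- small_panel(n_regions = 10, n_months = 24, seed = 29)
baseline_sc <- panel_sc[month_year(panel_sc$month) == 2019, ]

flat_projections <- function(baseline, years, growth = 0) {
  u <- baseline[!duplicated(baseline$region_id), ]
  do.call(rbind, lapply(seq_along(years), function(k) {
    pop <- u$population_scaled * 1e4 * (1 + growth)^k
    data.frame(region_id = u$region_id, year = years[k], population = pop,
               population_over_65 = pop * u$pct_over_65 / 100)
  }))
}

test_that("the future panel copies baseline and substitutes projections", {
  proj <- flat_projections(baseline_sc, 2020:2023)
  fut <- build_future_panel(baseline_sc, proj, 4)
  expect_equal(nrow(fut), 4 * nrow(baseline_sc))            # 480 rows
  expect_equal(length(unique(fut$month)), 48)               # 48 months
  # identity projections: rows differ from baseline only in labels
  one <- fut[fut$horizon_year == 1, ]
  for (v in mgsr_covariates()$all) {
    expect_equal(one[[v]], baseline_sc[[v]], tolerance = 1e-12)
  }
  expect_equal(month_year(one$month), rep(2020L, nrow(one)))

  grow <- build_future_panel(baseline_sc,
                             flat_projections(baseline_sc, 2020:2023, 0.01), 4)
  y2 <- grow[grow$horizon_year == 2, ]
  expect_equal(y2$population_scaled, baseline_sc$population_scaled * 1.01^2)
  expect_equal(y2$gp_capacity, baseline_sc$gp_capacity)     # held at baseline

  expect_error(build_future_panel(baseline_sc, proj[proj$year < 2023, ], 4),
               "missing projection")
  expect_error(build_future_panel(panel_sc, proj, 4), "one calendar year")
})

test_that("capacity uplifts scale one column and compose multiplicatively", {
  rows <- baseline_sc
  up <- apply_uplift(rows, "111", 0.10)
  expect_equal(up$capacity_111, rows$capacity_111 * 1.1)
  expect_equal(up$gp_capacity, rows$gp_capacity)
  expect_equal(apply_uplift(rows, "gp", 0)$gp_capacity, rows$gp_capacity)
  f <- 0.07; g <- 0.12
  twice <- apply_uplift(apply_uplift(rows, "ambulance", f), "ambulance", g)
  once <- apply_uplift(rows, "ambulance", (1 + f) * (1 + g) - 1)
  expect_equal(twice$ambulance_capacity, once$ambulance_capacity)
  expect_error(apply_uplift(rows, "dentist", 0.1), "unknown service")
})

test_that("the health ramp follows the stated arithmetic and caps at average", {
  rows <- data.frame(horizon_year = rep(1:3, 2),
                     people_index = rep(c(99.5, 104), each = 3),
                     places_index = 100, lives_index = 100)
  avgs <- c(people_index = 100, places_index = 100, lives_index = 100)
  out <- apply_health_ramp(rows, avgs, 0.2)
  expect_equal(out$people_index[1:3], c(99.7, 99.9, 100.0))  # capped in year 3
  expect_equal(out$people_index[4:6], c(104, 104, 104))      # above average
  expect_equal(out$places_index, rows$places_index)

  # closed form vs iterative application: years to reach the average
  set.seed(31)
  for (v0 in runif(10, 90, 99.9)) {
    years <- 0
    val <- v0
    while (val < 100) { years <- years + 1; val <- min(v0 + years * 0.2, 100) }
    expect_equal(years, ceiling((100 - v0) / 0.2))
  }
})

test_that("ramped values are monotone in the horizon and never overshoot", {
  proj <- flat_projections(baseline_sc, 2020:2023)
  fut <- build_future_panel(baseline_sc, proj, 4)
  avgs <- sapply(c("people_index", "places_index", "lives_index"), function(v)
    mean(baseline_sc[[v]][!duplicated(baseline_sc$region_id)]))
  out <- apply_health_ramp(fut, avgs, 0.2)
  for (v in names(avgs)) {
    ramped <- fut[[v]] < avgs[[v]]
    expect_true(all(out[[v]][ramped] <= avgs[[v]] + 1e-12))
    by_region <- split(out[c(v, "horizon_year")], fut$region_id)
    for (b in by_region) {
      expect_true(all(diff(tapply(b[[v]], b$horizon_year, mean)) >= -1e-12))
    }
  }
})

test_that("rolling mean matches the brute-force window oracle", {
  expect_equal(rolling_mean(rep(3, 10), 4), rep(3, 7))
  expect_equal(rolling_mean(c(1, 2, 3, 4), 4), 2.5)
  set.seed(33)
  x <- rnorm(40)
  oracle <- vapply(4:40, function(i) sum(x[(i - 3):i]) / 4, 0.0)
  expect_equal(rolling_mean(x, 4), oracle)
  expect_error(rolling_mean(1:3, 4), "shorter")
})

test_that("scenario forecasts respect identity, locality and shape", {
  model <- fit_mgsr(panel_sc, split = NULL, hyper_params(60, 0),
                    hyper_params(60, 0), seed = 7)
  proj <- flat_projections(baseline_sc, 2020:2023)
  dn <- forecast_scenario(model, baseline_sc, proj, scenario_spec("do_nothing"))
  expect_length(dn$mean_attendances, 48)
  expect_equal(length(dn$rolling), 60 - 3)
  expect_true(all(is.finite(dn$rolling)))
  # identity projections: every future year repeats the baseline predictions
  base_pred <- predict_mgsr(model, baseline_sc)
  base_means <- vapply(sort(unique(baseline_sc$month)), function(m)
    mean(base_pred[baseline_sc$month == m]), 0.0)
  expect_equal(dn$mean_attendances, rep(unname(base_means), 4),
               tolerance = 1e-9)
  # locality: uplifting a service leaves other scenarios' columns alone,
  # so do_nothing recomputed after an unrelated uplift is unchanged
  dn2 <- forecast_scenario(model, baseline_sc, proj,
                           scenario_spec("do_nothing"))
  expect_identical(dn$mean_attendances, dn2$mean_attendances)
})

test_that("improving population health lowers forecast demand", {
  lower <- 0
  for (s in 1:3) {
    p <- small_panel(n_regions = 20, n_months = 24, seed = 600 + s)
    b <- p[month_year(p$month) == 2019, ]
    model <- fit_mgsr(p, split = NULL, hyper_params(80, 0), hyper_params(80, 0),
                      seed = s)
    proj <- flat_projections(b, 2020:2023, 0.007)
    dn <- forecast_scenario(model, b, proj, scenario_spec("do_nothing"))
    hr <- forecast_scenario(model, b, proj, scenario_spec("health_ramp"))
    lower <- lower + (mean(hr$mean_attendances[13:48]) <=
                        mean(dn$mean_attendances[13:48]))
  }
  expect_gte(lower, 2)
})
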