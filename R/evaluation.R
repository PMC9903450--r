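#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`: the share of variance in `truth` explained by
#' the predictions. Undefined for a constant truth vector.
#'
#' @param truth Observed values (length >= 2, not constant).
#' @param predicted Predicted values, same length.
#' @return A number (<= 1; negative when worse than the mean).
#' @export
r_squared <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (length(truth) < 2) stop("need at least 2 observations")
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("R-squared is undefined for a constant truth vector")
  1 - sum((truth - predicted)^2) / ss_tot
}

#' Mean absolute percentage error
#'
#' Mean of `|truth - predicted| / truth`, reported as a fraction (0.03 =
#' 3%). Requires strictly positive truth values.
#'
#' @param truth Observed values, all > 0.
#' @param predicted Predicted values, same length.
#' @return Non-negative fraction.
#' @export
mape <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (any(truth <= 0)) stop("MAPE requires strictly positive truth values")
  mean(abs(truth - predicted) / truth)
}

#' Repeated k-fold cross-validation of the full stack
#'
#' For each repeat, rows are re-shuffled into nested 70/10/20 splits
#' (see [make_splits()]); for each fold the MGSR is fit and scored on
#' its validation rows. The default 5 repeats x 5 folds yield 25
#' distinct validation sets. Per-fold R-squared is also recorded for
#' each level-0 model alone, and a pooled R-squared (predictions of all
#' rows assembled from their validation fold, averaged over repeats) is
#' reported alongside the per-fold average.
#'
#' @param panel Curated panel rows.
#' @param n_repeats,n_folds Cross-validation design.
#' @param hp_capacity,hp_health Level-0 hyper-parameters.
#' @param seed Integer seed; each repeat derives its own shuffle seed.
#' @param tune If `TRUE`, level-0 hyper-parameters are re-selected once
#'   per repeat on the full data by [select_hyperparams()] (slower).
#' @return An `evaluation_report`: `folds` (one row per repeat-fold with
#'   `r2`, `r2_capacity`, `r2_health`, `mape`, coefficients), `r2_mean`,
#'   `r2_sd`, `mape_mean`, `pooled_r2`, and level-0 aggregates.
#' @export
cross_validate <- function(panel, n_repeats = 5L, n_folds = 5L,
                           hp_capacity = hyper_params(),
                           hp_health = hyper_params(),
                           seed = 0L, tune = FALSE) {
  rows <- list()
  pooled <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, rep_i)
    if (tune) {
      hp_capacity <- select_hyperparams(panel, "capacity", seed = rep_seed)
      hp_health <- select_hyperparams(annual_mean_target(panel), "health",
                                      seed = rep_seed)
    }
    splits <- make_splits(nrow(panel), n_folds, seed = rep_seed)
    pred_all <- rep(NA_real_, nrow(panel))
    for (split in splits) {
      model <- fit_mgsr(panel, split, hp_capacity, hp_health,
                        seed = derive_seed(rep_seed, split$fold_id))
      val <- panel[split$validation, , drop = FALSE]
      pred <- predict_mgsr(model, val)
      pred_all[split$validation] <- pred
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = rep_i, fold_id = split$fold_id,
        r2 = r_squared(val[[TARGET_VAR]], pred),
        r2_capacity = r_squared(val[[TARGET_VAR]],
                                predict(model$capacity_model, val)),
        r2_health = r_squared(val[[TARGET_VAR]],
                              predict(model$health_model, val)),
        mape = mape(val[[TARGET_VAR]], pred),
        beta0 = model$beta0, beta_capacity = model$beta_capacity,
        beta_health = model$beta_health)
    }
    pooled[rep_i] <- r_squared(panel[[TARGET_VAR]], pred_all)
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 r2_mean = mean(folds$r2), r2_sd = sd(folds$r2),
                 r2_capacity_mean = mean(folds$r2_capacity),
                 r2_health_mean = mean(folds$r2_health),
                 mape_mean = mean(folds$mape),
                 pooled_r2 = mean(pooled),
                 n_repeats = n_repeats, n_folds = n_folds, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Repeated %d x %d-fold cross-validation (%d validation sets)\n",
              x$n_repeats, x$n_folds, nrow(x$folds)))
  cat(sprintf("  MGSR      R2 = %.3f +/- %.3f  (pooled %.3f)\n",
              x$r2_mean, x$r2_sd, x$pooled_r2))
  cat(sprintf("  capacity  R2 = %.3f\n", x$r2_capacity_mean))
  cat(sprintf("  health    R2 = %.3f\n", x$r2_health_mean))
  cat(sprintf("  MAPE = %.1f%%\n", 100 * x$mape_mean))
  invisible(x)
}

#' Year-ahead forecasting accuracy
#'
#' Fits the MGSR to one calendar year of the panel (all rows used for
#' both stacking levels) and forecasts the next. Accuracy is measured on
#' the mean monthly attendance rate across regions: MAPE over the test
#' year's months, the per-month percent errors, and the winter
#' (December-February) mean absolute percent error.
#'
#' @param panel Curated panel rows covering both years.
#' @param train_year,test_year Calendar years.
#' @param hp_capacity,hp_health Level-0 hyper-parameters.
#' @param seed Integer seed.
#' @return A `forecast_accuracy` list: `mape`, `winter_error`,
#'   `monthly_errors` (signed fractions, named by month), `truth_series`,
#'   `predicted_series`, plus the fitted model.
#' @export
forecast_accuracy <- function(panel, train_year, test_year,
                              hp_capacity = hyper_params(),
                              hp_health = hyper_params(), seed = 0L) {
  yr <- month_year(panel$month)
  train <- panel[yr == train_year, , drop = FALSE]
  test <- panel[yr == test_year, , drop = FALSE]
  if (!nrow(train)) stop("no panel rows for train year ", train_year)
  if (!nrow(test)) stop("no panel rows for test year ", test_year)

  model <- fit_mgsr(train, split = NULL, hp_capacity, hp_health, seed = seed)
  pred <- predict_mgsr(model, test)

  months <- sort(unique(test$month))
  truth_series <- vapply(months, function(m) {
    mean(test[[TARGET_VAR]][test$month == m]) }, 0.0)
  pred_series <- vapply(months, function(m) {
    mean(pred[test$month == m]) }, 0.0)
  err <- (pred_series - truth_series) / truth_series
  winter <- month_num(months) %in% c(12L, 1L, 2L)
  structure(list(mape = mean(abs(err)),
                 winter_error = mean(abs(err[winter])),
                 monthly_errors = stats::setNames(err, months),
                 truth_series = stats::setNames(truth_series, months),
                 predicted_series = stats::setNames(pred_series, months),
                 model = model,
                 train_year = train_year, test_year = test_year),
            class = "forecast_accuracy")
}

#' @export
print.forecast_accuracy <- function(x, ...) {
  cat(sprintf("Forecast %d -> %d: MAPE %.1f%%, winter error %.1f%%\n",
              x$train_year, x$test_year, 100 * x$mape, 100 * x$winter_error))
  invisible(x)
}

# permute annual covariates at region-year level, then broadcast, so all
# months of a region-year receive the same permuted value
permute_covariate <- function(rows, var) {
  if (var %in% HEALTH_VARS) {
    key <- paste(rows$region_id, month_year(rows$month))
    u <- unique(key)
    vals <- rows[[var]][match(u, key)]
    rows[[var]] <- vals[sample(length(u))][match(key, u)]
  } else {
    rows[[var]] <- rows[[var]][sample(nrow(rows))]
  }
  rows
}

#' Stack-wide permutation importance
#'
#' For every covariate: refit-free validation-set permutation. Within
#' each fold of a repeated 5-fold cross-validation, the fitted stack is
#' held fixed, the covariate is permuted within the validation rows
#' (annual covariates at region-year level, then broadcast), and the
#' importance is the drop in R-squared relative to the unpermuted
#' validation predictions. Reported as mean and standard deviation over
#' all folds and repeats, alongside each level-0 model's impurity (Gini)
#' importances averaged over folds.
#'
#' @param panel Curated panel rows.
#' @param n_repeats,n_folds Cross-validation design.
#' @param hp_capacity,hp_health Level-0 hyper-parameters.
#' @param seed Integer seed.
#' @param extra_vars Optional extra panel columns to include (e.g. a
#'   known-null covariate in simulation studies); they are permuted and
#'   scored like the 8 model covariates.
#' @return An `importance_report`: `permutation` (data frame with
#'   `variable`, `pi_mean`, `pi_sd`), `gini` (per model), `r2_base`.
#' @export
permutation_importance <- function(panel, n_repeats = 5L, n_folds = 5L,
                                   hp_capacity = hyper_params(),
                                   hp_health = hyper_params(),
                                   seed = 0L, extra_vars = character(0)) {
  vars <- c(ALL_COVARIATES, extra_vars)
  pi_vals <- matrix(NA_real_, nrow = n_repeats * n_folds, ncol = length(vars),
                    dimnames = list(NULL, vars))
  gini_c <- NULL
  gini_h <- NULL
  base_r2 <- numeric(0)
  row_i <- 0L
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, rep_i)
    splits <- make_splits(nrow(panel), n_folds, seed = rep_seed)
    for (split in splits) {
      row_i <- row_i + 1L
      model <- fit_mgsr(panel, split, hp_capacity, hp_health,
                        seed = derive_seed(rep_seed, split$fold_id))
      val <- panel[split$validation, , drop = FALSE]
      r2_0 <- r_squared(val[[TARGET_VAR]], predict_mgsr(model, val))
      base_r2 <- c(base_r2, r2_0)
      set.seed(derive_seed(rep_seed, 5000L + split$fold_id))
      for (v in vars) {
        perm <- permute_covariate(val, v)
        pi_vals[row_i, v] <- r2_0 -
          r_squared(val[[TARGET_VAR]], predict_mgsr(model, perm))
      }
      gini_c <- rbind(gini_c, gini_importance(model$capacity_model))
      gini_h <- rbind(gini_h, gini_importance(model$health_model))
    }
  }
  permutation <- data.frame(variable = vars,
                            pi_mean = colMeans(pi_vals),
                            pi_sd = apply(pi_vals, 2, sd),
                            row.names = NULL)
  structure(list(permutation = permutation,
                 gini = list(capacity = colMeans(gini_c),
                             health = colMeans(gini_h)),
                 r2_base = mean(base_r2),
                 per_fold = pi_vals,
                 n_repeats = n_repeats, n_folds = n_folds, seed = seed),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Permutation importance (mean +/- sd over",
      nrow(x$per_fold), "folds):\n")
  p <- x$permutation[order(-x$permutation$pi_mean), ]
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-20s %6.3f +/- %.3f\n", p$variable[i], p$pi_mean[i],
                p$pi_sd[i]))
  }
  invisible(x)
}
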