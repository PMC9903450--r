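#' Hyper-parameters for a level-0 forest
#'
#' The two tuned hyper-parameters are the number of trees and the maximum
#' tree depth (`0` = unbounded).
#'
#' @param n_trees Positive integer.
#' @param max_depth Positive integer, or `0` for unbounded trees.
#' @return A `hyper_params` list.
#' @export
hyper_params <- function(n_trees = 200L, max_depth = 0L) {
  stopifnot(n_trees >= 1, max_depth >= 0)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth)),
            class = "hyper_params")
}

#' Default hyper-parameter search grid
#'
#' @return List of [hyper_params()]: n_trees in {50, 100, 200, 500} by
#'   max_depth in {2, 4, 8, unbounded}.
#' @export
default_hp_grid <- function() {
  grid <- expand.grid(n_trees = c(50L, 100L, 200L, 500L),
                      max_depth = c(2L, 4L, 8L, 0L))
  lapply(seq_len(nrow(grid)),
         function(i) hyper_params(grid$n_trees[i], grid$max_depth[i]))
}

fit_level0 <- function(rows, predictors, target, role, hp, seed) {
  check_columns(rows, c(predictors, target), paste(role, "training rows"))
  if (nrow(rows) < 2) stop("need at least 2 rows to fit the ", role, " model")
  if (anyNA(rows[c(predictors, target)])) {
    stop("missing values in ", role, " training rows; curate first")
  }
  # all features tried at every split: the regression default of the
  # reference toolchain, and more accurate at these low dimensions
  forest <- reg_forest(rows[predictors], rows[[target]],
                       n_trees = hp$n_trees, max_depth = hp$max_depth,
                       mtry = length(predictors), seed = seed)
  structure(list(forest = forest, role = role, predictors = predictors,
                 target = target, hyper = hp, seed = as.integer(seed)),
            class = "level0_model")
}

#' Fit the capacity model
#'
#' Level-0 random forest at monthly granularity: predicts the monthly ED
#' attendance rate from the three service-capacity rates (GP
#' appointments, 111 calls offered, ambulance calls answered, all per
#' 10,000).
#'
#' @param rows Curated panel rows (region-months), no missing values.
#' @param hp A [hyper_params()].
#' @param seed Integer seed.
#' @return A `level0_model`.
#' @export
fit_capacity <- function(rows, hp = hyper_params(), seed = 0L) {
  fit_level0(rows, CAPACITY_VARS, TARGET_VAR, "capacity", hp, seed)
}

#' Fit the population-health model
#'
#' Level-0 random forest at annual granularity: predicts the annual mean
#' of the monthly ED attendance rate from population (scaled), % over
#' 65 and the three Health-Index domains. Fit on one row per
#' region-year (see [annual_mean_target()]); its monthly use is by
#' broadcast, since the five covariates are constant within a
#' region-year.
#'
#' @param annual_rows Output of [annual_mean_target()] (or any rows with
#'   the five health covariates and `annual_mean_attendances`).
#' @param hp A [hyper_params()].
#' @param seed Integer seed.
#' @return A `level0_model`.
#' @export
fit_health <- function(annual_rows, hp = hyper_params(), seed = 0L) {
  fit_level0(annual_rows, HEALTH_VARS, "annual_mean_attendances", "health",
             hp, seed)
}

#' Predict from a level-0 model
#'
#' Predictions are bounded by the training-target range by construction
#' (forests average training responses and cannot extrapolate).
#'
#' @param object A `level0_model`.
#' @param newdata Rows carrying the model's predictor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.level0_model <- function(object, newdata, ...) {
  predict(object$forest, newdata)
}

#' @export
print.level0_model <- function(x, ...) {
  cat("Level-0", x$role, "model (random forest, ",
      x$hyper$n_trees, " trees, depth ",
      if (x$hyper$max_depth == 0) "unbounded" else x$hyper$max_depth, ")\n",
      sep = "")
  print(round(gini_importance(x), 3))
  invisible(x)
}

#' Select level-0 hyper-parameters by cross-validation
#'
#' Evaluates every grid point with k-fold cross-validation and applies
#' the one-standard-deviation rule: among points whose mean validation
#' R-squared is within one standard deviation of the best point's mean,
#' the least complex (fewest trees, then shallowest; unbounded depth is
#' deepest) is selected. This operationalizes "maximise mean validation
#' performance while minimising model complexity".
#'
#' @param rows Training rows for the model being tuned.
#' @param role `"capacity"` or `"health"` (chooses predictors/target).
#' @param grid List of [hyper_params()].
#' @param n_folds Folds of the tuning cross-validation.
#' @param seed Integer seed (drives fold assignment and forest fits).
#' @return The selected `hyper_params`, with the full score table
#'   attached as attribute `"scores"`.
#' @export
select_hyperparams <- function(rows, role = c("capacity", "health"),
                               grid = default_hp_grid(), n_folds = 5L,
                               seed = 0L) {
  role <- match.arg(role)
  if (!length(grid)) stop("empty hyper-parameter grid")
  predictors <- if (role == "capacity") CAPACITY_VARS else HEALTH_VARS
  target <- if (role == "capacity") TARGET_VAR else "annual_mean_attendances"
  check_columns(rows, c(predictors, target), "tuning rows")
  n <- nrow(rows)
  if (n < 2 * n_folds) stop("too few rows to tune with ", n_folds, " folds")

  set.seed(derive_seed(seed, 104729L))
  fold <- sample(rep(seq_len(n_folds), length.out = n))

  scores <- lapply(seq_along(grid), function(g) {
    hp <- grid[[g]]
    r2 <- vapply(seq_len(n_folds), function(f) {
      train <- rows[fold != f, , drop = FALSE]
      test <- rows[fold == f, , drop = FALSE]
      # the same per-fold seed for every grid point, so grid points whose
      # settings are behaviourally identical score identically (exact ties)
      fit <- fit_level0(train, predictors, target, role, hp,
                        seed = derive_seed(seed, f))
      r_squared(test[[target]], predict(fit, test))
    }, 0.0)
    data.frame(n_trees = hp$n_trees, max_depth = hp$max_depth,
               r2_mean = mean(r2), r2_sd = sd(r2))
  })
  scores <- do.call(rbind, scores)

  best <- which.max(scores$r2_mean)
  eligible <- scores$r2_mean >= scores$r2_mean[best] - scores$r2_sd[best]
  # least complex among eligible: fewest trees, then shallowest
  depth_key <- ifelse(scores$max_depth == 0L, Inf, scores$max_depth)
  ord <- order(!eligible, scores$n_trees, depth_key)
  pick <- ord[1]
  out <- hyper_params(scores$n_trees[pick], scores$max_depth[pick])
  attr(out, "scores") <- scores
  out
}
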