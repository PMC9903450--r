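#' Nested split plans for repeated 5-fold cross-validation
#'
#' Rows are shuffled once per repeat and cut into `n_folds` folds. For
#' each fold the held-out fold is the validation set (20% with 5 folds);
#' the remainder (the training set) is split 7/8 : 1/8 into level-0 rows
#' (70% of all data) and level-1 combiner rows (10%). Across one
#' repeat's folds every row is validated exactly once. Splitting is over
#' rows (region-months) without grouping by region, matching the
#' evaluation protocol the model mirrors; the month-to-month leakage this
#' implies within a region is a documented property, not corrected.
#'
#' @param n Number of panel rows (>= 10).
#' @param n_folds Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of `split_plan`s, one per fold, each with integer index
#'   vectors `level0`, `level1`, `validation` plus `fold_id` and `seed`.
#' @export
make_splits <- function(n, n_folds = 5L, seed = 0L) {
  if (n < 10) stop("too few rows to build a nested split (need >= 10)")
  if (n_folds < 2 || n_folds > n) stop("invalid number of folds")
  set.seed(derive_seed(seed, 15485863L))
  perm <- sample(n)
  bounds <- floor(seq(0, n, length.out = n_folds + 1))
  lapply(seq_len(n_folds), function(f) {
    validation <- perm[(bounds[f] + 1):bounds[f + 1]]
    train <- perm[-((bounds[f] + 1):bounds[f + 1])]
    n_l1 <- round(length(train) / 8)
    structure(list(level0 = sort(train[-seq_len(n_l1)]),
                   level1 = sort(train[seq_len(n_l1)]),
                   validation = sort(validation),
                   fold_id = f, seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Fit the multi-granular stacked regression
#'
#' The capacity model is fit to the level-0 rows at monthly granularity;
#' the population-health model is fit, independently, to annual mean
#' targets derived from the level-0 rows only (partial region-years use
#' the mean of their available months, so no validation information
#' leaks in). The level-1 combiner is an ordinary-least-squares
#' regression, with intercept, of the monthly attendance rate on the two
#' level-0 predictions over the level-1 rows.
#'
#' @param panel Curated panel rows.
#' @param split A `split_plan` from [make_splits()], or `NULL` to fit
#'   every stage on all rows (the configuration used to refit the model
#'   to the entire data set before forecasting).
#' @param hp_capacity,hp_health [hyper_params()] for the two forests.
#' @param seed Integer seed driving both forest fits.
#' @param capacity_model,health_model Optional pre-fitted stand-ins for
#'   the level-0 models (any object with a `predict` method); used for
#'   stub-based verification of the combiner.
#' @return An `mgsr_model`: the two level-0 models and combiner
#'   coefficients `beta0`, `beta_capacity`, `beta_health`.
#' @export
fit_mgsr <- function(panel, split = NULL,
                     hp_capacity = hyper_params(),
                     hp_health = hyper_params(),
                     seed = 0L,
                     capacity_model = NULL, health_model = NULL) {
  if (is.null(split)) {
    idx_all <- seq_len(nrow(panel))
    split <- structure(list(level0 = idx_all, level1 = idx_all,
                            validation = integer(0), fold_id = 0L,
                            seed = as.integer(seed)),
                       class = "split_plan")
  }
  l0 <- panel[split$level0, , drop = FALSE]
  l1 <- panel[split$level1, , drop = FALSE]
  if (is.null(capacity_model)) {
    capacity_model <- fit_capacity(l0, hp_capacity, seed = derive_seed(seed, 1L))
  }
  if (is.null(health_model)) {
    annual <- annual_mean_target(l0)
    health_model <- fit_health(annual, hp_health, seed = derive_seed(seed, 2L))
  }
  pred_c <- predict(capacity_model, l1)
  pred_h <- predict(health_model, l1)
  fit <- lm.fit(cbind(intercept = 1, capacity = pred_c, health = pred_h),
                l1[[TARGET_VAR]])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0   # collinear level-0 predictions: drop the alias
  structure(list(capacity_model = capacity_model,
                 health_model = health_model,
                 beta0 = unname(beta[1]),
                 beta_capacity = unname(beta[2]),
                 beta_health = unname(beta[3]),
                 split = split[c("fold_id", "seed")]),
            class = "mgsr_model")
}

#' Predict monthly attendance rates from a fitted MGSR
#'
#' `y_hat = beta0 + beta_capacity * c_hat + beta_health * h_hat`, where
#' `c_hat` is the monthly capacity-model prediction and `h_hat` the
#' population-health prediction, which is constant across the months of
#' a region-year (the annual covariates it sees are), i.e. the annual
#' prediction broadcast to every month.
#'
#' @param model An `mgsr_model`.
#' @param rows Rows carrying all 8 covariates.
#' @return Numeric vector of predicted monthly attendance rates.
#' @export
predict_mgsr <- function(model, rows) {
  stopifnot(inherits(model, "mgsr_model"))
  if (nrow(rows) == 0L) return(numeric(0))
  model$beta0 +
    model$beta_capacity * predict(model$capacity_model, rows) +
    model$beta_health * predict(model$health_model, rows)
}

#' @export
predict.mgsr_model <- function(object, newdata, ...) predict_mgsr(object, newdata)

#' @export
print.mgsr_model <- function(x, ...) {
  cat("Multi-granular stacked regression\n")
  cat(sprintf("  combiner: y = %.3f + %.3f * capacity + %.3f * health\n",
              x$beta0, x$beta_capacity, x$beta_health))
  invisible(x)
}

#' Save / load a fitted MGSR as a self-describing JSON archive
#'
#' The archive carries predictor names, hyper-parameters, target ranges
#' and the full tree data of both forests, so forecasts are reproducible
#' across sessions without compiled state.
#'
#' @param model An `mgsr_model`.
#' @param path Archive path (JSON).
#' @return `save_mgsr`: invisibly, `path`; `load_mgsr`: the restored
#'   `mgsr_model`.
#' @export
save_mgsr <- function(model, path) {
  stopifnot(inherits(model, "mgsr_model"))
  strip <- function(m) {
    if (!inherits(m, "level0_model")) {
      stop("only forest-backed models can be archived")
    }
    list(role = m$role, predictors = m$predictors, target = m$target,
         hyper = unclass(m$hyper), seed = m$seed,
         forest = list(trees = m$forest$trees,
                       importance = as.list(m$forest$importance),
                       predictors = m$forest$predictors,
                       target_range = m$forest$target_range,
                       hyper = m$forest$hyper))
  }
  payload <- list(format = "mgsr-archive-1",
                  beta0 = model$beta0,
                  beta_capacity = model$beta_capacity,
                  beta_health = model$beta_health,
                  capacity_model = strip(model$capacity_model),
                  health_model = strip(model$health_model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mgsr
#' @export
load_mgsr <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(p$format, "mgsr-archive-1")) stop("not an MGSR archive: ", path)
  revive <- function(m) {
    forest <- structure(
      list(trees = m$forest$trees,
           importance = unlist(m$forest$importance),
           predictors = m$forest$predictors,
           target_range = m$forest$target_range,
           hyper = m$forest$hyper),
      class = "reg_forest")
    structure(list(forest = forest, role = m$role, predictors = m$predictors,
                   target = m$target,
                   hyper = structure(m$hyper[c("n_trees", "max_depth")],
                                     class = "hyper_params"),
                   seed = m$seed),
              class = "level0_model")
  }
  structure(list(capacity_model = revive(p$capacity_model),
                 health_model = revive(p$health_model),
                 beta0 = p$beta0, beta_capacity = p$beta_capacity,
                 beta_health = p$beta_health,
                 split = NULL),
            class = "mgsr_model")
}
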