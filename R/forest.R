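#' Fit a regression random forest
#'
#' Bagged CART regression trees with variance-reduction splits and a random
#' feature subset considered at every split. The implementation is internal
#' to the package (compiled) and fully deterministic given `seed`; trees
#' are stored as flat numeric vectors so fitted forests survive JSON
#' round-trips.
#'
#' @param x Data frame or numeric matrix of predictors (no missing values).
#' @param y Numeric response, one value per row of `x`.
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth; `NULL` (or `0`) grows unbounded trees.
#' @param mtry Features tried per split; default `max(1, floor(p / 3))`,
#'   the usual regression-forest heuristic.
#' @param min_split Minimum node size eligible for splitting.
#' @param min_leaf Minimum rows in a child node.
#' @param seed Integer seed for the forest's private RNG stream.
#'
#' @return An object of class `reg_forest`: trees, normalized impurity
#'   (Gini-type) importances, predictor names, training-target range and
#'   the hyper-parameters used.
#' @export
reg_forest <- function(x, y, n_trees = 100L, max_depth = NULL, mtry = NULL,
                       min_split = 2L, min_leaf = 1L, seed = 0L) {
  xm <- as_predictor_matrix(x)
  y <- as.numeric(y)
  if (nrow(xm) != length(y)) stop("x and y have different lengths")
  if (anyNA(xm) || anyNA(y)) {
    stop("missing values in training data; curation must precede fitting")
  }
  if (is.null(max_depth)) max_depth <- 0L
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(xm) / 3))
  fit <- .forest_fit_cpp(xm, y, as.integer(n_trees), as.integer(max_depth),
                         as.integer(mtry), as.integer(min_split),
                         as.integer(min_leaf), as.integer(seed))
  importance <- as.numeric(fit$importance)
  names(importance) <- colnames(xm)
  structure(
    list(trees = fit$trees,
         importance = importance,
         predictors = colnames(xm),
         target_range = range(y),
         hyper = list(n_trees = as.integer(n_trees),
                      max_depth = as.integer(max_depth),
                      mtry = as.integer(mtry),
                      min_split = as.integer(min_split),
                      min_leaf = as.integer(min_leaf),
                      seed = as.integer(seed))),
    class = "reg_forest")
}

#' Predict from a regression forest
#'
#' Predictions are means of training-leaf means, so they always lie within
#' the training-target range: the forest cannot extrapolate beyond the
#' response values seen during fitting.
#'
#' @param object A `reg_forest`.
#' @param newdata Data frame or matrix containing the model's predictors.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.reg_forest <- function(object, newdata, ...) {
  xm <- as_predictor_matrix(newdata, required = object$predictors)
  if (nrow(xm) == 0L) return(numeric(0))
  .forest_predict_cpp(object$trees, xm)
}

#' @export
print.reg_forest <- function(x, ...) {
  cat("Regression random forest:", length(x$trees), "trees on",
      length(x$predictors), "predictors\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("  target range: [", format(x$target_range[1]), ",",
      format(x$target_range[2]), "]\n")
  invisible(x)
}

#' Normalized impurity importance of a fitted forest
#'
#' @param object A `reg_forest` (or a level-0 model wrapping one).
#' @return Named numeric vector summing to 1.
#' @export
gini_importance <- function(object) {
  if (inherits(object, "level0_model")) object <- object$forest
  if (!inherits(object, "reg_forest")) stop("not a fitted forest")
  object$importance
}

# Coerce predictors to a numeric matrix, checking the required columns
# exist. Column order follows `required` when given so a forest always
# sees features in its training order.
as_predictor_matrix <- function(x, required = NULL) {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x)) stop("predictors must be a data frame or matrix")
  if (!is.null(required)) {
    missing_cols <- setdiff(required, names(x))
    if (length(missing_cols)) {
      stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
    }
    x <- x[required]
  }
  if (nrow(x) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = ncol(x),
                  dimnames = list(NULL, names(x))))
  }
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stop("predictors must be numeric")
  storage.mode(xm) <- "double"
  xm
}
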