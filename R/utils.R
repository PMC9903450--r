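`%||%` <- function(a, b) if (is.null(a)) b else a

#' Month label helpers
#'
#' Months are carried as ISO "YYYY-MM" labels in files and converted to a
#' 0-based integer index from the study start internally. The calendar
#' month is never a model predictor; the index only orders observations.
#'
#' @param month Character vector of "YYYY-MM" labels.
#' @param origin Origin label mapped to index 0.
#' @return `month_index`: integer vector; `month_year`: integer years;
#'   `month_num`: integer calendar months 1-12; `month_seq`: character
#'   vector of `n` consecutive labels; `month_shift`: labels shifted by
#'   `k` months.
#' @name months
NULL

#' @rdname months
#' @export
month_index <- function(month, origin) {
  check_month(c(month, origin))
  12L * (month_year(month) - month_year(origin)) +
    (month_num(month) - month_num(origin))
}

#' @rdname months
#' @export
month_year <- function(month) as.integer(substr(month, 1, 4))

#' @rdname months
#' @export
month_num <- function(month) as.integer(substr(month, 6, 7))

#' @rdname months
#' @param start First label of the sequence.
#' @param n Number of months.
#' @export
month_seq <- function(start, n) {
  check_month(start)
  m0 <- 12L * month_year(start) + (month_num(start) - 1L)
  m <- m0 + seq_len(n) - 1L
  sprintf("%04d-%02d", m %/% 12L, m %% 12L + 1L)
}

#' @rdname months
#' @param k Signed number of months to shift by.
#' @export
month_shift <- function(month, k) {
  check_month(month)
  m <- 12L * month_year(month) + (month_num(month) - 1L) + as.integer(k)
  sprintf("%04d-%02d", m %/% 12L, m %% 12L + 1L)
}

check_month <- function(month) {
  bad <- !grepl("^\\d{4}-(0[1-9]|1[0-2])$", month)
  if (any(bad)) {
    stop("malformed month label(s): ",
         paste(unique(month[bad]), collapse = ", "), " (expected YYYY-MM)")
  }
  invisible(month)
}

check_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  invisible(df)
}

# stable group-sum returning a data.frame; base aggregate() drops NA groups
# and reorders, so do it by hand with a deterministic key order
group_sum <- function(df, keys, value) {
  key <- interaction(df[keys], drop = TRUE, lex.order = TRUE)
  sums <- tapply(df[[value]], key, sum)
  parts <- df[!duplicated(key), keys, drop = FALSE]
  parts <- parts[order(interaction(parts[keys], drop = TRUE, lex.order = TRUE)), ,
                 drop = FALSE]
  out <- data.frame(parts, value = as.numeric(sums[levels(key)]),
                    row.names = NULL, check.names = FALSE)
  names(out)[ncol(out)] <- value
  out
}
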