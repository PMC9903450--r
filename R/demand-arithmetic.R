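#' Demand-growth arithmetic
#'
#' Small helpers for the worked arithmetic of national demand growth:
#' the percentage rise between two demand levels, and the annual cost
#' implied by a rise in mean daily attendances at a fixed unit cost.
#'
#' @param from,to Mean daily attendances at the start and end of the
#'   comparison period.
#' @return `percent_change`: the rise in percent;
#'   `annual_cost_increase`: the extra annual spend implied,
#'   `(to - from) * cost_per_attendance * 365`, in the unit cost's
#'   currency.
#' @export
percent_change <- function(from, to) {
  if (any(from <= 0)) stop("baseline value must be positive")
  100 * (to - from) / from
}

#' @rdname percent_change
#' @param cost_per_attendance Unit cost of one attendance.
#' @export
annual_cost_increase <- function(from, to, cost_per_attendance) {
  (to - from) * cost_per_attendance * 365
}
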