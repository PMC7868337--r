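#' Unit conversions between clearance and concentration scales
#'
#' The neonatal nephrology literature mixes ml/min and L/day for clearance,
#' and mg/dl and mg/L for creatinine concentration. These helpers are exact
#' inverse pairs (1 day = 1440 min; 1 L = 10 dl).
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @examples
#' ml_per_min_to_l_per_day(0.0094) # 0.013536 L/day
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
ml_per_min_to_l_per_day <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * 1440 / 1000
}

#' @rdname unit-conversions
#' @export
l_per_day_to_ml_per_min <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * 1000 / 1440
}

#' @rdname unit-conversions
#' @export
mg_dl_to_mg_l <- function(x) x * 10

#' @rdname unit-conversions
#' @export
mg_l_to_mg_dl <- function(x) x / 10
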