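#' Model parameters for the creatinine maturation model
#'
#' Bundles every coefficient of the clearance-maturation and concentration
#' dynamics for one neonate, with units fixed by convention:
#'
#' * `cl_bl_raw` (L/day): baseline clearance before covariate scaling
#'   (reference value 0.075 L/day).
#' * `baseline_covariate_factor` (dimensionless): multiplier applied to
#'   `cl_bl_raw`; the reference parameterisation uses 1 + 2.55 = 3.55, so
#'   the effective baseline clearance entering the model is
#'   `cl_bl_raw * baseline_covariate_factor` = 0.26625 L/day.
#' * `emax` (L/day): maximum additional clearance gained through postnatal
#'   maturation (gestational-age specific).
#' * `t50` (days): postnatal age at which half of `emax` is reached.
#' * `hill` (dimensionless, > 0): steepness of the maturation curve.
#' * `vd_per_kg` (L/kg): distribution volume per kg body weight (0.7).
#' * `production_rate` (mg/day): constant endogenous creatinine input.
#' * `ibuprofen_reduction` (L/day): absolute clearance reduction while an
#'   ibuprofen course is active (0.0094 ml/min = 0.013536 L/day).
#' * `clearance_floor` (L/day): positivity floor applied after the
#'   ibuprofen subtraction; never binding in calibrated scenarios.
#'
#' @param emax maximum additional clearance, L/day.
#' @param t50 postnatal age at half-maximal additional clearance, days.
#' @param hill Hill coefficient, dimensionless.
#' @param production_rate endogenous creatinine input, mg/day.
#' @param cl_bl_raw baseline clearance before covariate scaling, L/day.
#' @param baseline_covariate_factor dimensionless baseline multiplier.
#' @param vd_per_kg distribution volume per kg, L/kg.
#' @param ibuprofen_reduction absolute clearance reduction under ibuprofen,
#'   L/day.
#' @param clearance_floor minimum clearance after the reduction, L/day.
#' @return An object of class `model_parameters`.
#' @export
#' @examples
#' p <- model_parameters(emax = 0.5, t50 = 12, hill = 1.5,
#'                       production_rate = 2.4)
#' baseline_clearance(p) # 0.26625 L/day
model_parameters <- function(emax,
                             t50,
                             hill,
                             production_rate,
                             cl_bl_raw = 0.075,
                             baseline_covariate_factor = 3.55,
                             vd_per_kg = 0.7,
                             ibuprofen_reduction = ml_per_min_to_l_per_day(0.0094),
                             clearance_floor = 1e-6) {
  p <- list(
    cl_bl_raw = as.numeric(cl_bl_raw),
    baseline_covariate_factor = as.numeric(baseline_covariate_factor),
    emax = as.numeric(emax),
    t50 = as.numeric(t50),
    hill = as.numeric(hill),
    vd_per_kg = as.numeric(vd_per_kg),
    production_rate = as.numeric(production_rate),
    ibuprofen_reduction = as.numeric(ibuprofen_reduction),
    clearance_floor = as.numeric(clearance_floor)
  )
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

validate_model_parameters <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("cl_bl_raw", "baseline_covariate_factor", "emax", "t50",
              "hill", "vd_per_kg", "production_rate",
              "ibuprofen_reduction", "clearance_floor")) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite scalar")
  }
  if (p$cl_bl_raw <= 0) stop("cl_bl_raw must be > 0")
  if (p$baseline_covariate_factor <= 0)
    stop("baseline_covariate_factor must be > 0")
  if (p$emax < 0) stop("emax must be >= 0")
  if (p$t50 <= 0) stop("t50 must be > 0")
  if (p$hill <= 0) stop("hill must be > 0")
  if (p$vd_per_kg <= 0) stop("vd_per_kg must be > 0")
  if (p$production_rate < 0) stop("production_rate must be >= 0")
  if (p$ibuprofen_reduction < 0) stop("ibuprofen_reduction must be >= 0")
  if (p$clearance_floor <= 0) stop("clearance_floor must be > 0")
  invisible(p)
}

#' Effective baseline clearance
#'
#' The clearance at birth (postnatal age 0), i.e. the covariate-scaled
#' baseline `cl_bl_raw * baseline_covariate_factor`.
#'
#' @param params a [model_parameters()] object.
#' @return Baseline clearance in L/day.
#' @export
baseline_clearance <- function(params) {
  params$cl_bl_raw * params$baseline_covariate_factor
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Creatinine model parameters\n")
  cat(sprintf("  baseline clearance : %.5f L/day (%.3f x %.2f)\n",
              baseline_clearance(x), x$cl_bl_raw,
              x$baseline_covariate_factor))
  cat(sprintf("  emax               : %.4f L/day\n", x$emax))
  cat(sprintf("  t50                : %.3f days\n", x$t50))
  cat(sprintf("  hill               : %.3f\n", x$hill))
  cat(sprintf("  vd_per_kg          : %.2f L/kg\n", x$vd_per_kg))
  cat(sprintf("  production_rate    : %.4f mg/day\n", x$production_rate))
  cat(sprintf("  ibuprofen_reduction: %.6f L/day (%.4f ml/min)\n",
              x$ibuprofen_reduction,
              l_per_day_to_ml_per_min(x$ibuprofen_reduction)))
  invisible(x)
}
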