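# Packaged reference constants and configuration handling.

.neocreat_cache <- new.env(parent = emptyenv())

#' Load a model configuration
#'
#' Reads a structured YAML configuration (model constants, reference
#' neonates, treatment periods, calibration and cohort settings). With no
#' argument, returns the packaged default configuration, which encodes the
#' four reference neonates and the reference model constants.
#'
#' @param path path to a YAML configuration file, or `NULL` for the
#'   packaged default.
#' @return A nested list with components `model`, `reference_neonates`,
#'   `treatment_periods`, `calibration` and `cohort`.
#' @export
default_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "neocreat", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("model", "reference_neonates", "treatment_periods")) {
    if (is.null(cfg[[key]]))
      stop("configuration is missing required section '", key, "'")
  }
  cfg
}

#' Reference neonate profiles
#'
#' The four typical ELBW reference neonates (gestational ages 24, 27, 29
#' and 32 weeks; birth weights 621, 779, 840 and 889 g; initial creatinine
#' 0.383, 0.462, 0.518 and 0.607 mg/dl).
#'
#' @param config a configuration list from [default_config()].
#' @return A list of [neonate_profile()] objects.
#' @export
reference_profiles <- function(config = default_config()) {
  lapply(config$reference_neonates, function(n) {
    neonate_profile(id = n$id,
                    gestational_age = n$gestational_age,
                    birth_weight = n$birth_weight,
                    initial_creatinine = n$initial_creatinine,
                    bsa_day1 = n$bsa_day1 %||% NA_real_,
                    bsa_day31 = n$bsa_day31 %||% NA_real_)
  })
}

#' Reference treatment periods
#'
#' The three 3-day ibuprofen courses: calendar days 1-3, 15-17 and 29-31,
#' dosed 10/5/5 mg/kg at 24 h intervals.
#'
#' @inheritParams reference_profiles
#' @return A list of [treatment_course()] objects.
#' @export
reference_courses <- function(config = default_config()) {
  lapply(config$treatment_periods, function(p) {
    treatment_course(start_day = p$start_day,
                     duration_days = p$duration_days,
                     doses_mg_per_kg = unlist(p$doses_mg_per_kg))
  })
}

#' Packaged trajectory anchor points
#'
#' The reference serum creatinine concentrations at the boundaries of the
#' three treatment windows (postnatal days 0, 3, 14, 17, 28, 31) for the
#' four reference gestational ages, by treatment arm. The no-ibuprofen set
#' (24 points) is the calibration input; the t = 0 point of each
#' gestational age doubles as the initial condition.
#'
#' @param arm `"no_ibuprofen"` (default), `"ibuprofen"`, or `"both"`.
#' @return A data frame with columns `ga_weeks`, `time_day`, `arm`,
#'   `concentration_mg_dl`.
#' @export
reference_anchors <- function(arm = c("no_ibuprofen", "ibuprofen", "both")) {
  arm <- match.arg(arm)
  path <- system.file("extdata", "reference_anchors.csv",
                      package = "neocreat", mustWork = TRUE)
  anchors <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (arm != "both") anchors <- anchors[anchors$arm == arm, , drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

#' Reference end-of-course concentration differences
#'
#' The reference between-arm serum creatinine differences (ibuprofen minus
#' no ibuprofen, mg/dl) at the end of each treatment period, per
#' gestational age. Used for out-of-sample validation of the calibrated
#' model, never for fitting.
#'
#' @return A data frame with columns `ga_weeks`, `period`,
#'   `difference_mg_dl`.
#' @export
reference_differences <- function() {
  path <- system.file("extdata", "reference_differences.csv",
                      package = "neocreat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference birth weight (g) as a function of gestational age, linear
# interpolation between the four reference neonates (constant beyond).
typical_weight <- function(ga, scale = 1) {
  stats::approx(x = c(24, 27, 29, 32),
                y = c(621, 779, 840, 889) * scale,
                xout = ga, rule = 2)$y
}

# Reference initial creatinine (mg/dl) as a function of gestational age.
typical_initial_creatinine <- function(ga) {
  stats::approx(x = c(24, 27, 29, 32),
                y = c(0.383, 0.462, 0.518, 0.607),
                xout = ga, rule = 2)$y
}

model_parameters_from_config <- function(cfg_model, emax, t50, hill,
                                         production_rate) {
  model_parameters(
    emax = emax, t50 = t50, hill = hill,
    production_rate = production_rate,
    cl_bl_raw = cfg_model$cl_bl_raw,
    baseline_covariate_factor = cfg_model$baseline_covariate_factor,
    vd_per_kg = cfg_model$vd_per_kg,
    ibuprofen_reduction =
      ml_per_min_to_l_per_day(cfg_model$ibuprofen_reduction_ml_min),
    clearance_floor = cfg_model$clearance_floor)
}
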