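#' Neonate profile
#'
#' Describes one reference or virtual ELBW neonate. Delivery mode is carried
#' as an inert covariate slot (its effect size is not parameterised here);
#' body-surface-area values are optional metadata and never enter the
#' computation. Weight is held at birth weight over the simulation horizon.
#'
#' @param id short label.
#' @param gestational_age gestational age at birth, completed weeks (22-34).
#' @param birth_weight birth weight, grams.
#' @param initial_creatinine serum creatinine at birth, mg/dl.
#' @param delivery_mode one of `"vaginal"`, `"c_section"`, `"unspecified"`.
#' @param bsa_day1,bsa_day31 optional body surface area, m^2.
#' @return An object of class `neonate_profile`.
#' @export
#' @examples
#' neonate_profile("GA24", 24, 621, 0.383)
neonate_profile <- function(id,
                            gestational_age,
                            birth_weight,
                            initial_creatinine,
                            delivery_mode = c("unspecified", "vaginal",
                                              "c_section"),
                            bsa_day1 = NA_real_,
                            bsa_day31 = NA_real_) {
  delivery_mode <- match.arg(delivery_mode)
  stopifnot(length(gestational_age) == 1L, length(birth_weight) == 1L,
            length(initial_creatinine) == 1L)
  if (!is.finite(birth_weight) || birth_weight <= 0)
    stop("birth_weight must be > 0 g")
  if (!is.finite(initial_creatinine) || initial_creatinine <= 0)
    stop("initial_creatinine must be > 0 mg/dl")
  if (!is.finite(gestational_age) || gestational_age < 22 ||
      gestational_age > 34)
    stop("gestational_age must lie in 22-34 weeks")
  structure(
    list(id = as.character(id),
         gestational_age = as.numeric(gestational_age),
         birth_weight = as.numeric(birth_weight),
         delivery_mode = delivery_mode,
         initial_creatinine = as.numeric(initial_creatinine),
         bsa_day1 = as.numeric(bsa_day1),
         bsa_day31 = as.numeric(bsa_day31)),
    class = "neonate_profile")
}

#' @export
print.neonate_profile <- function(x, ...) {
  cat(sprintf("Neonate %s: GA %g wk, %g g, SCr(0) %.3f mg/dl (%s delivery)\n",
              x$id, x$gestational_age, x$birth_weight,
              x$initial_creatinine, x$delivery_mode))
  invisible(x)
}

#' Ibuprofen treatment course
#'
#' A course of once-daily ibuprofen doses. `start_day` is the 1-based
#' calendar day of the first dose; calendar day d spans postnatal time
#' (d-1, d] days, so a course starting on day 1 with a 3-day duration is
#' active over postnatal time \[0, 3\]. Dose amounts follow the label
#' (10, 5, 5 mg/kg at 24 h intervals); they are recorded as metadata only —
#' exposure is binary and dose size never enters the creatinine dynamics.
#'
#' @param start_day calendar day of first dose (>= 1).
#' @param duration_days number of consecutive treatment days (>= 1).
#' @param doses_mg_per_kg per-day doses, mg/kg; length must equal
#'   `duration_days`.
#' @return An object of class `treatment_course`.
#' @export
#' @examples
#' treatment_course(start_day = 15)           # days 15-17
#' treatment_course(1, 3, c(10, 5, 5))        # first week course
treatment_course <- function(start_day,
                             duration_days = 3L,
                             doses_mg_per_kg = c(10, 5, 5)) {
  start_day <- as.integer(start_day)
  duration_days <- as.integer(duration_days)
  if (is.na(start_day) || start_day < 1L) stop("start_day must be >= 1")
  if (is.na(duration_days) || duration_days < 1L)
    stop("duration_days must be >= 1")
  if (length(doses_mg_per_kg) != duration_days)
    stop("doses_mg_per_kg must have one entry per treatment day")
  structure(
    list(start_day = start_day,
         duration_days = duration_days,
         doses_mg_per_kg = as.numeric(doses_mg_per_kg)),
    class = "treatment_course")
}

# Exposure window in postnatal time: [start, end] days since birth.
course_window <- function(course) {
  start <- course$start_day - 1
  c(start = start, end = start + course$duration_days)
}

#' @export
print.treatment_course <- function(x, ...) {
  w <- course_window(x)
  cat(sprintf("Ibuprofen course: days %d-%d (t in [%g, %g] d), doses %s mg/kg\n",
              x$start_day, x$start_day + x$duration_days - 1L,
              w["start"], w["end"],
              paste(x$doses_mg_per_kg, collapse = "/")))
  invisible(x)
}
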