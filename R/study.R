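# Replication of the reference simulation study: four reference neonates
# x three treatment periods x two arms over a 6-week horizon.

#' Build the reference scenario grid
#'
#' The 4 x 3 grid of reference neonates (GA 24/27/29/32 weeks) and 3-day
#' ibuprofen courses (calendar days 1-3, 15-17, 29-31). Each
#' (neonate, period) scenario carries exactly one course: periods are
#' independent scenarios, with no carry-over between them.
#'
#' @param config configuration list from [default_config()].
#' @return A `scenario_grid`: list with `profiles` (4 profiles), `periods`
#'   (3 courses) and `horizon` (days).
#' @export
build_reference_grid <- function(config = default_config()) {
  structure(list(profiles = reference_profiles(config),
                 periods = reference_courses(config),
                 horizon = config$model$horizon_day %||% 42),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("Scenario grid: %d neonates x %d treatment periods, %g-day horizon\n",
              length(x$profiles), length(x$periods), x$horizon))
  invisible(x)
}

#' Run the reference simulation study
#'
#' Simulates every scenario of the grid in both arms with calibrated
#' parameters and extracts the summary tables: before/after
#' concentrations at the treatment-window boundaries per gestational age,
#' period and arm; the between-arm end-of-course differences; and the
#' concentration and clearance trajectories underlying the figures. The
#' no-ibuprofen trajectory per gestational age is computed once and
#' shared across periods.
#'
#' @param result a converged `calibration_result` from
#'   [calibrate_model()]; default the cached packaged calibration.
#' @param grid a `scenario_grid`; default [build_reference_grid()].
#' @param step integration step, days.
#' @return A `study_tables` object: list with
#'   * `table1`: `ga_weeks`, `period`, `difference_mg_dl` (3 decimals,
#'     round-half-to-even) and `difference_unrounded`;
#'   * `table2`: `ga_weeks`, `period`, `arm`, `before_mg_dl`,
#'     `after_mg_dl` (3 decimals);
#'   * `table2_unrounded`: same layout, unrounded;
#'   * `fig1_data` (concentration) and `fig2_data` (clearance):
#'     `ga_weeks`, `arm`, `period` (`NA` for the shared no-ibuprofen
#'     curve), `time_day`, value column.
#' @export
run_study <- function(result = default_calibration(),
                      grid = build_reference_grid(result$config),
                      step = result$refine_step %||% 0.005) {
  if (!isTRUE(result$converged))
    stop("calibration did not converge; refusing to run the study")
  horizon <- grid$horizon
  t1 <- list(); t2 <- list(); conc <- list(); clear <- list()

  for (prof in grid$profiles) {
    ga <- prof$gestational_age
    params <- result$parameters[[as.character(ga)]]
    if (is.null(params)) stop("no calibrated parameters for GA ", ga)
    ctrl <- simulate_concentration(prof, params, list(), horizon, step)
    conc[[length(conc) + 1L]] <-
      data.frame(ga_weeks = ga, arm = "no_ibuprofen", period = NA_integer_,
                 time_day = ctrl$time_day,
                 concentration_mg_dl = ctrl$concentration_mg_dl)
    clear[[length(clear) + 1L]] <-
      data.frame(ga_weeks = ga, arm = "no_ibuprofen", period = NA_integer_,
                 time_day = ctrl$time_day,
                 clearance_l_day = ctrl$clearance_l_day)

    for (p in seq_along(grid$periods)) {
      course <- grid$periods[[p]]
      w <- course_window(course)
      ibu <- simulate_concentration(prof, params, list(course), horizon,
                                    step)
      before <- trajectory_at(ctrl, w[["start"]])
      stopifnot(abs(before - trajectory_at(ibu, w[["start"]])) < 1e-12)
      after_ctrl <- trajectory_at(ctrl, w[["end"]])
      after_ibu <- trajectory_at(ibu, w[["end"]])
      t1[[length(t1) + 1L]] <-
        data.frame(ga_weeks = ga, period = p,
                   difference_unrounded = after_ibu - after_ctrl)
      t2[[length(t2) + 1L]] <-
        data.frame(ga_weeks = ga, period = rep(p, 2L),
                   arm = c("ibuprofen", "no_ibuprofen"),
                   before_mg_dl = rep(before, 2L),
                   after_mg_dl = c(after_ibu, after_ctrl))
      conc[[length(conc) + 1L]] <-
        data.frame(ga_weeks = ga, arm = "ibuprofen", period = p,
                   time_day = ibu$time_day,
                   concentration_mg_dl = ibu$concentration_mg_dl)
      clear[[length(clear) + 1L]] <-
        data.frame(ga_weeks = ga, arm = "ibuprofen", period = p,
                   time_day = ibu$time_day,
                   clearance_l_day = ibu$clearance_l_day)
    }
  }

  table1 <- do.call(rbind, t1)
  table1$difference_mg_dl <- round(table1$difference_unrounded, 3)
  table1 <- table1[, c("ga_weeks", "period", "difference_mg_dl",
                       "difference_unrounded")]
  table2_unrounded <- do.call(rbind, t2)
  table2 <- table2_unrounded
  table2$before_mg_dl <- round(table2$before_mg_dl, 3)
  table2$after_mg_dl <- round(table2$after_mg_dl, 3)

  structure(list(table1 = table1, table2 = table2,
                 table2_unrounded = table2_unrounded,
                 fig1_data = do.call(rbind, conc),
                 fig2_data = do.call(rbind, clear),
                 step = step),
            class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat("Reference study replication\n")
  cat("\nEnd-of-course differences, ibuprofen minus no ibuprofen (mg/dl):\n")
  wide <- stats::reshape(x$table1[, c("ga_weeks", "period",
                                      "difference_mg_dl")],
                         idvar = "ga_weeks", timevar = "period",
                         direction = "wide")
  names(wide) <- c("ga_weeks", paste0("period_", 1:3))
  print(wide, row.names = FALSE)
  cat("\nBefore/after concentrations (mg/dl) per arm: see $table2\n")
  invisible(x)
}

#' Proportional clearance reduction under ibuprofen
#'
#' The signed percent change of creatinine clearance caused by the
#' constant absolute ibuprofen reduction at postnatal age `t`:
#' `-100 * ibuprofen_reduction / CL(t)`. Because clearance matures
#' upward, the magnitude shrinks with postnatal age — at birth it is
#' about -5%, by week 5 about -2%.
#'
#' @param t postnatal age, days (vectorised).
#' @param params a [model_parameters()] object.
#' @return Signed percent change (negative values).
#' @export
proportional_reduction <- function(t, params) {
  -100 * params$ibuprofen_reduction / maturation_clearance(t, params)
}
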