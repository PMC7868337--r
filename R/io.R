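# CSV readers/writers for the package's exchange formats.

#' Write and read trajectory CSV files
#'
#' Trajectories are exchanged as CSV with header
#' `time_day,concentration_mg_dl,clearance_l_day,exposed`
#' (`exposed` coded 0/1), one file per scenario.
#'
#' @param traj a trajectory from [simulate_concentration()].
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a data frame in trajectory layout.
#' @export
write_trajectory <- function(traj, path) {
  out <- data.frame(time_day = traj$time_day,
                    concentration_mg_dl = traj$concentration_mg_dl,
                    clearance_l_day = traj$clearance_l_day,
                    exposed = as.integer(traj$exposed))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  need <- c("time_day", "concentration_mg_dl", "clearance_l_day", "exposed")
  df <- read_checked_csv(path, need)
  df$exposed <- df$exposed != 0
  df
}

#' Write and read anchor-point CSV files
#'
#' Anchor sets are exchanged as CSV with header
#' `ga_weeks,time_day,arm,concentration_mg_dl`.
#'
#' @param anchors anchor data frame (see [reference_anchors()]).
#' @param path file path.
#' @return `write_anchors()` returns `path` invisibly; `read_anchors()`
#'   returns the anchor data frame.
#' @export
write_anchors <- function(anchors, path) {
  need <- c("ga_weeks", "time_day", "arm", "concentration_mg_dl")
  stopifnot(all(need %in% names(anchors)))
  utils::write.csv(anchors[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  read_checked_csv(path, c("ga_weeks", "time_day", "arm",
                           "concentration_mg_dl"))
}

# read.csv with a column check that reports the offending file.
read_checked_csv <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed CSV '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CSV '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Serialise a calibration result
#'
#' Writes the fitted parameters as a machine-readable CSV
#' (`calibration_parameters.csv`: one row per gestational age plus the
#' shared shape values) and a plain-text report with units, objective and
#' the residual table.
#'
#' @param result a `calibration_result`.
#' @param dir output directory (created if absent).
#' @return The parameter CSV path, invisibly.
#' @export
write_calibration <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  est <- result$estimates
  est_path <- file.path(dir, "calibration_parameters.csv")
  utils::write.csv(est, est_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(result$residuals,
                   file.path(dir, "calibration_residuals.csv"),
                   row.names = FALSE, quote = FALSE)
  rpt <- c(
    "Creatinine maturation model calibration report",
    sprintf("converged: %s (%d starts)", result$converged, result$n_starts),
    sprintf("objective (sum of squared residuals): %.6e mg/dl^2",
            result$objective),
    sprintf("RMS residual: %.6f mg/dl",
            sqrt(mean(result$residuals$residual^2))),
    sprintf("shape at GA %g wk: t50 %.4f d, hill %.4f; GA slopes %.5f, %.5f per wk",
            result$ga_ref, result$shape[["t50_ref"]],
            result$shape[["hill_ref"]], result$shape[["t50_slope"]],
            result$shape[["hill_slope"]]),
    "",
    "per-GA estimates (emax L/day, production_rate mg/day, t50 d):",
    utils::capture.output(print(est, row.names = FALSE)))
  writeLines(rpt, file.path(dir, "calibration_report.txt"))
  invisible(est_path)
}

#' Read back calibrated parameters
#'
#' Reads a `calibration_parameters.csv` written by [write_calibration()]
#' and rebuilds the per-gestational-age [model_parameters()] list.
#'
#' @param path path to the CSV.
#' @param config model-constant configuration.
#' @return Named list of [model_parameters()] keyed by gestational age.
#' @export
read_calibration_parameters <- function(path, config = default_config()) {
  est <- read_checked_csv(path, c("ga_weeks", "emax", "production_rate",
                                  "t50", "hill"))
  out <- lapply(seq_len(nrow(est)), function(i) {
    model_parameters_from_config(config$model, emax = est$emax[i],
                                 t50 = est$t50[i], hill = est$hill[i],
                                 production_rate = est$production_rate[i])
  })
  names(out) <- as.character(est$ga_weeks)
  out
}

#' Write a synthetic cohort
#'
#' Observations go to `cohort_observations.csv` (header
#' `id,ga_weeks,weight_g,time_day,creatinine_mg_dl,exposed`), the
#' per-neonate ground truth to `cohort_ground_truth.csv`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return The observation CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obs <- cohort$observations
  obs$exposed <- as.integer(obs$exposed)
  obs_path <- file.path(dir, "cohort_observations.csv")
  utils::write.csv(obs, obs_path, row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  gt$exposed <- as.integer(gt$exposed)
  utils::write.csv(gt, file.path(dir, "cohort_ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(obs_path)
}

#' Write the study tables
#'
#' Emits `table1.csv` (`ga_weeks,period,difference_mg_dl`), `table2.csv`
#' (`ga_weeks,period,arm,before_mg_dl,after_mg_dl`), their unrounded
#' companions, and one trajectory CSV per gestational age and arm
#' (`trajectory_ga<GA>_<arm>.csv`; the ibuprofen file stacks the three
#' period scenarios with a `period` column).
#'
#' @param tables a `study_tables` object from [run_study()].
#' @param dir output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_study_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  emit(tables$table1[, c("ga_weeks", "period", "difference_mg_dl")],
       "table1.csv")
  emit(tables$table2[, c("ga_weeks", "period", "arm", "before_mg_dl",
                         "after_mg_dl")], "table2.csv")
  emit(tables$table1[, c("ga_weeks", "period", "difference_unrounded")],
       "table1_unrounded.csv")
  emit(tables$table2_unrounded, "table2_unrounded.csv")
  f1 <- tables$fig1_data
  f2 <- tables$fig2_data
  for (ga in unique(f1$ga_weeks)) {
    for (arm in c("no_ibuprofen", "ibuprofen")) {
      sel1 <- f1$ga_weeks == ga & f1$arm == arm
      sel2 <- f2$ga_weeks == ga & f2$arm == arm
      df <- data.frame(period = f1$period[sel1],
                       time_day = f1$time_day[sel1],
                       concentration_mg_dl = f1$concentration_mg_dl[sel1],
                       clearance_l_day = f2$clearance_l_day[sel2])
      emit(df, sprintf("trajectory_ga%d_%s.csv", ga, arm))
    }
  }
  invisible(paths)
}
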