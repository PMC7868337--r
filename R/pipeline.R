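# Pipeline driver tying the stages together; used by the command-line
# wrapper in inst/scripts/neocreat.

#' Run a pipeline stage
#'
#' Executes one named stage with a resolved configuration and writes its
#' artifacts plus a run manifest (`manifest.yaml`: package version,
#' command, seed, input checksums and the resolved configuration) to
#' `output_dir`. Stages:
#'
#' * `"calibrate"`: fit the maturation parameters to the anchor set
#'   (packaged by default, or `anchors_csv`) and write the calibration
#'   report, parameter CSV and the out-of-sample treatment-effect
#'   validation table.
#' * `"replicate-study"`: run the 4 x 3 x 2 reference study with the
#'   calibrated parameters (recomputed, or read from a previous
#'   `calibrate` output via `parameters_csv`) and write `table1.csv`,
#'   `table2.csv` and the per-scenario trajectory CSVs.
#' * `"simulate"`: simulate the reference neonates without treatment and
#'   write one trajectory CSV each.
#' * `"generate-cohort"`: write a synthetic cohort and its ground truth.
#' * `"recovery"`: run a simulation-estimation recovery experiment and
#'   write the per-parameter error summary.
#'
#' No stage mutates its inputs; outputs are refused if present unless
#' `force` is set.
#'
#' @param command stage name.
#' @param output_dir directory for artifacts (created if absent).
#' @param config_path optional YAML configuration overriding the packaged
#'   default.
#' @param seed integer seed for the stochastic stages.
#' @param force overwrite existing outputs.
#' @param anchors_csv optional anchor CSV for `calibrate`.
#' @param parameters_csv optional `calibration_parameters.csv` from a
#'   previous `calibrate` run, consumed by `replicate-study` and
#'   `simulate`.
#' @param n_neonates,n_replicates sizes for the cohort stages.
#' @param quiet suppress progress messages.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(command = c("calibrate", "replicate-study",
                                     "simulate", "generate-cohort",
                                     "recovery"),
                         output_dir,
                         config_path = NULL,
                         seed = 1L,
                         force = FALSE,
                         anchors_csv = NULL,
                         parameters_csv = NULL,
                         n_neonates = NULL,
                         n_replicates = 3L,
                         quiet = FALSE) {
  command <- match.arg(command)
  if (missing(output_dir) || !nzchar(output_dir))
    stop("output_dir is required")
  config <- default_config(config_path)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  guard <- function(paths) {
    hit <- paths[file.exists(paths)]
    if (length(hit) && !force)
      stop("refusing to overwrite existing output (use force = TRUE): ",
           paste(basename(hit), collapse = ", "))
  }

  inputs <- c(config = config_path, anchors = anchors_csv,
              parameters = parameters_csv)
  written <- character(0)

  get_result <- function() {
    if (!is.null(parameters_csv)) {
      pars <- read_calibration_parameters(parameters_csv, config)
      est <- utils::read.csv(parameters_csv, stringsAsFactors = FALSE)
      return(list(parameters = pars, estimates = est, config = config,
                  converged = TRUE, refine_step = NULL))
    }
    if (is.null(anchors_csv) && is.null(config_path)) {
      # identical to a fresh fit on the packaged defaults, but cached
      return(default_calibration())
    }
    anchors <- if (is.null(anchors_csv)) reference_anchors() else
      read_anchors(anchors_csv)
    if ("arm" %in% names(anchors))
      anchors <- anchors[anchors$arm == "no_ibuprofen", , drop = FALSE]
    calibrate_model(anchors = anchors, config = config)
  }

  if (command == "calibrate") {
    out <- file.path(output_dir, c("calibration_parameters.csv",
                                   "calibration_residuals.csv",
                                   "calibration_report.txt",
                                   "treatment_effect_validation.csv"))
    guard(out)
    say("calibrating maturation parameters (", default_start_grid(config) |>
          nrow(), " starts) ...")
    result <- get_result()
    write_calibration(result, output_dir)
    val <- validate_treatment_effect(result, config)
    utils::write.csv(val, out[4], row.names = FALSE, quote = FALSE)
    written <- out
  } else if (command == "replicate-study") {
    result <- get_result()
    if (is.null(result$shape)) {
      tables <- run_study_from_parameters(result, config)
    } else {
      tables <- run_study(result)
    }
    out <- file.path(output_dir,
                     c("table1.csv", "table2.csv", "table1_unrounded.csv",
                       "table2_unrounded.csv",
                       sprintf("trajectory_ga%d_%s.csv",
                               rep(vapply(reference_profiles(config),
                                          `[[`, numeric(1),
                                          "gestational_age"), each = 2L),
                               c("no_ibuprofen", "ibuprofen"))))
    guard(out)
    written <- write_study_tables(tables, output_dir)
  } else if (command == "simulate") {
    result <- get_result()
    profiles <- reference_profiles(config)
    out <- file.path(output_dir,
                     sprintf("trajectory_%s.csv",
                             vapply(profiles, `[[`, character(1), "id")))
    guard(out)
    for (i in seq_along(profiles)) {
      prof <- profiles[[i]]
      params <- result$parameters[[as.character(prof$gestational_age)]]
      traj <- simulate_concentration(prof, params, list(),
                                     config$model$horizon_day %||% 42,
                                     config$model$step_day %||% 0.005)
      write_trajectory(traj, out[i])
    }
    written <- out
  } else if (command == "generate-cohort") {
    out <- file.path(output_dir, c("cohort_observations.csv",
                                   "cohort_ground_truth.csv"))
    guard(out)
    spec <- cohort_spec(n_neonates = n_neonates, seed = seed,
                        config = config)
    cohort <- generate_cohort(spec, default_calibration())
    write_cohort(cohort, output_dir)
    written <- out
  } else if (command == "recovery") {
    out <- file.path(output_dir, c("recovery_errors.csv",
                                   "recovery_summary.csv"))
    guard(out)
    spec <- cohort_spec(n_neonates = n_neonates, seed = seed,
                        config = config)
    rep <- recovery_experiment(spec, n_replicates = n_replicates)
    utils::write.csv(rep$errors, out[1], row.names = FALSE, quote = FALSE)
    utils::write.csv(rep$summary, out[2], row.names = FALSE, quote = FALSE)
    written <- out
  }

  manifest <- list(
    package = "neocreat",
    version = as.character(utils::packageVersion("neocreat")),
    command = command,
    seed = as.integer(seed),
    inputs = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    outputs = basename(written),
    config = config)
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  say("wrote ", length(written), " artifact(s) to ", output_dir)
  invisible(c(written, file.path(output_dir, "manifest.yaml")))
}

# Study replication from a bare per-GA parameter list (no shape info),
# as read back from a calibration CSV.
run_study_from_parameters <- function(result, config) {
  res <- list(parameters = result$parameters, config = config,
              converged = TRUE, refine_step = config$model$step_day %||%
                0.005)
  class(res) <- "calibration_result"
  run_study(result = res, grid = build_reference_grid(config),
            step = config$model$step_day %||% 0.005)
}
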