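# Virtual ELBW cohort generation and simulation-estimation recovery.

#' Specification of a virtual ELBW cohort
#'
#' Describes the structure the generator emulates: a cohort of 217 ELBW
#' neonates contributing about 4,026 serum creatinine samples over the
#' first 6 weeks of life, with median gestational age 27 weeks (IQR
#' 26-28) and median birth weight 830 g (IQR 720-910).
#'
#' @param n_neonates cohort size.
#' @param seed integer seed; every random draw derives from it.
#' @param config configuration list providing the cohort defaults.
#' @param samples_mean Poisson mean of the per-neonate sample count; one
#'   mandatory day-0 sample is added on top.
#' @param ga_support,ga_prob discrete gestational-age distribution
#'   (weeks).
#' @param weight_sdlog lognormal dispersion of birth weight given GA.
#' @param bsv_cv lognormal coefficients of variation for the
#'   between-subject variability of `emax`, `production_rate` and the
#'   baseline-clearance multiplier (`cl_bl`).
#' @param residual_prop,residual_add proportional and additive (mg/dl)
#'   residual-error standard deviations.
#' @param exposure_fraction probability that a neonate receives a 3-day
#'   ibuprofen course.
#' @param exposure_start_day calendar start day of that course.
#' @param horizon sampling horizon, days.
#' @param sim_step integration step used for the ground-truth
#'   trajectories, days.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_neonates = NULL,
                        seed = 1L,
                        config = default_config(),
                        samples_mean = NULL,
                        ga_support = NULL,
                        ga_prob = NULL,
                        weight_sdlog = NULL,
                        bsv_cv = NULL,
                        residual_prop = NULL,
                        residual_add = NULL,
                        exposure_fraction = NULL,
                        exposure_start_day = NULL,
                        horizon = NULL,
                        sim_step = 0.02) {
  cc <- config$cohort
  spec <- list(
    n_neonates = as.integer(n_neonates %||% cc$n_neonates %||% 217L),
    seed = as.integer(seed),
    samples_mean = samples_mean %||% cc$samples_mean %||% 17.6,
    ga_support = as.numeric(unlist(ga_support %||% cc$ga_support)),
    ga_prob = as.numeric(unlist(ga_prob %||% cc$ga_prob)),
    weight_median_scale = cc$weight_median_scale %||% 1,
    weight_sdlog = weight_sdlog %||% cc$weight_sdlog %||% 0.17,
    bsv_cv = lapply(bsv_cv %||% cc$bsv_cv, as.numeric),
    residual_prop = residual_prop %||% cc$residual_prop %||% 0.05,
    residual_add = residual_add %||% cc$residual_add %||% 0.01,
    exposure_fraction = exposure_fraction %||% cc$exposure_fraction %||% 0.3,
    exposure_start_day = as.integer(exposure_start_day %||%
                                      cc$exposure_start_day %||% 1L),
    horizon = horizon %||% cc$horizon_day %||% 42,
    sim_step = sim_step)
  if (spec$n_neonates < 1L) stop("n_neonates must be >= 1")
  if (length(spec$ga_support) != length(spec$ga_prob))
    stop("ga_support and ga_prob must have equal length")
  if (any(spec$ga_prob < 0) || sum(spec$ga_prob) <= 0)
    stop("ga_prob must be a non-negative weight vector")
  for (f in c("weight_sdlog", "residual_prop", "residual_add"))
    if (spec[[f]] < 0) stop(f, " must be >= 0")
  if (any(unlist(spec$bsv_cv) < 0)) stop("bsv coefficients must be >= 0")
  if (spec$exposure_fraction < 0 || spec$exposure_fraction > 1)
    stop("exposure_fraction must lie in [0, 1]")
  structure(spec, class = "cohort_spec")
}

# Median-one lognormal deviates from a coefficient of variation
# (pharmacometric convention: the typical value is the median).
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Generate a virtual ELBW cohort
#'
#' Draws neonates (gestational age, birth weight, individual model
#' parameters), simulates their ground-truth creatinine trajectories with
#' the calibrated typical parameters scaled by lognormal between-subject
#' variability, samples each trajectory at random clinical times (plus a
#' mandatory birth sample) and perturbs the samples with
#' proportional-plus-additive measurement noise, truncated so observed
#' concentrations stay positive (any draw at or below 0.01 mg/dl is
#' redrawn). The generator is fully deterministic given `spec$seed`, and
#' each neonate's records depend only on its own random substream, so
#' neonates are mutually independent.
#'
#' @param spec a [cohort_spec()].
#' @param result a converged `calibration_result` supplying the typical
#'   parameters; default the cached packaged calibration.
#' @return A `synthetic_cohort`: list with `observations` (data frame
#'   `id`, `ga_weeks`, `weight_g`, `time_day`, `creatinine_mg_dl`,
#'   `exposed`), `ground_truth` (per-neonate true parameters and exposure
#'   assignment; kept separate from the observations so it can never leak
#'   into fitting inputs) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            result = default_calibration()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_neonates
  cfg_model <- result$config$model
  duration <- 3L
  w_start <- spec$exposure_start_day - 1
  w_end <- w_start + duration
  horizon <- spec$horizon
  step <- spec$sim_step

  # cohort-level draws
  set.seed(spec$seed)
  ga <- sample(spec$ga_support, n, replace = TRUE,
               prob = spec$ga_prob / sum(spec$ga_prob))
  typ <- interpolate_parameters(result, ga)
  med_w <- typical_weight(ga, scale = spec$weight_median_scale)

  # per-neonate substreams keep neonates mutually independent
  sub_seed <- (spec$seed + 104729 * seq_len(n)) %% 2147483647L

  cv <- spec$bsv_cv
  id <- sprintf("N%04d", seq_len(n))
  weight <- numeric(n)
  eta_emax <- numeric(n); eta_prod <- numeric(n); eta_clbl <- numeric(n)
  exposed <- logical(n)
  t_obs_list <- vector("list", n)
  noise_list <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seed[i])
    weight[i] <- med_w[i] * stats::rlnorm(1, 0, spec$weight_sdlog)
    eta_emax[i] <- rlnorm_cv(1, cv$emax %||% 0)
    eta_prod[i] <- rlnorm_cv(1, cv$production_rate %||% 0)
    eta_clbl[i] <- rlnorm_cv(1, cv$cl_bl %||% 0)
    exposed[i] <- stats::runif(1) < spec$exposure_fraction
    n_obs <- 1L + stats::rpois(1, spec$samples_mean)
    t_obs_list[[i]] <- c(0, sort(stats::runif(n_obs - 1L, 0, horizon)))
    # a bank of noise draws per sample; later draws redo truncated ones
    noise_list[[i]] <- matrix(stats::rnorm(2L * n_obs * 25L),
                              nrow = 2L * n_obs, ncol = 25L)
  }

  emax_i <- vapply(typ, `[[`, numeric(1), "emax") * eta_emax
  prod_i <- vapply(typ, `[[`, numeric(1), "production_rate") * eta_prod
  t50_i <- vapply(typ, `[[`, numeric(1), "t50")
  hill_i <- vapply(typ, `[[`, numeric(1), "hill")
  cl_bl_i <- cfg_model$cl_bl_raw * cfg_model$baseline_covariate_factor *
    eta_clbl
  c0 <- typical_initial_creatinine(ga)
  vd_l <- cfg_model$vd_per_kg * weight / 1000
  delta <- ml_per_min_to_l_per_day(cfg_model$ibuprofen_reduction_ml_min)

  # one vectorised integration across the whole cohort
  n_steps <- round(horizon / step)
  times <- seq(0, by = step, length.out = n_steps + 1L)
  stage_times <- seq(0, by = step / 2, length.out = 2L * n_steps + 1L)
  cl_stage <- vapply(seq_len(n), function(i) {
    cl_bl_i[i] + emax_i[i] * hill_fraction(stage_times, t50_i[i], hill_i[i])
  }, numeric(length(stage_times)))
  k_stage <- sweep(cl_stage, 2L, vd_l, "/")
  t_lo <- times[-length(times)]
  t_hi <- times[-1L]
  in_window <- t_lo >= w_start - 1e-9 & t_hi <= w_end + 1e-9
  kred_step <- outer(as.numeric(in_window), exposed * delta / vd_l)
  conc <- rk4_linear(c0 = c0, u = prod_i / (10 * vd_l),
                     k_stage = k_stage, h = step, kred_step = kred_step,
                     k_floor = cfg_model$clearance_floor / vd_l)

  obs_list <- vector("list", n)
  for (i in seq_len(n)) {
    t_obs <- t_obs_list[[i]]
    n_obs <- length(t_obs)
    c_true <- stats::approx(times, conc[, i], xout = t_obs)$y
    noise <- noise_list[[i]]
    y <- c_true * (1 + spec$residual_prop * noise[seq_len(n_obs), 1L]) +
      spec$residual_add * noise[n_obs + seq_len(n_obs), 1L]
    for (col in 2:ncol(noise)) {
      bad <- y <= 0.01
      if (!any(bad)) break
      y[bad] <- c_true[bad] *
        (1 + spec$residual_prop * noise[seq_len(n_obs), col][bad]) +
        spec$residual_add * noise[n_obs + seq_len(n_obs), col][bad]
    }
    y[y <= 0.01] <- 0.01 + spec$residual_add
    obs_list[[i]] <- data.frame(
      id = id[i], ga_weeks = ga[i], weight_g = weight[i],
      time_day = t_obs, creatinine_mg_dl = y,
      exposed = exposed[i] & t_obs >= w_start & t_obs <= w_end)
  }

  ground_truth <- data.frame(
    id = id, ga_weeks = ga, weight_g = weight, initial_creatinine = c0,
    emax = emax_i, production_rate = prod_i,
    cl_bl_raw = cfg_model$cl_bl_raw * eta_clbl, t50 = t50_i,
    hill = hill_i, exposed = exposed)

  structure(list(observations = do.call(rbind, obs_list),
                 ground_truth = ground_truth,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  o <- x$observations
  cat(sprintf("Synthetic ELBW cohort: %d neonates, %d creatinine samples\n",
              nrow(x$ground_truth), nrow(o)))
  cat(sprintf("  GA median %g wk (IQR %g-%g); weight median %.0f g (IQR %.0f-%.0f)\n",
              stats::median(x$ground_truth$ga_weeks),
              stats::quantile(x$ground_truth$ga_weeks, 0.25, type = 1),
              stats::quantile(x$ground_truth$ga_weeks, 0.75, type = 1),
              stats::median(x$ground_truth$weight_g),
              stats::quantile(x$ground_truth$weight_g, 0.25),
              stats::quantile(x$ground_truth$weight_g, 0.75)))
  cat(sprintf("  exposed to ibuprofen: %d neonates\n",
              sum(x$ground_truth$exposed)))
  invisible(x)
}

#' Simulation-estimation parameter recovery
#'
#' For each replicate: generate a cohort, pool the unexposed neonates'
#' observations into per-gestational-age anchor sets, refit the model
#' with [calibrate_model()], and compare the recovered typical parameters
#' (per-GA `emax`, `production_rate`, `t50`, `hill`) against the
#' generating values. Gestational-age groups with fewer than
#' `min_neonates` unexposed neonates are dropped from the fit.
#'
#' @param spec a [cohort_spec()]; replicate `r` uses `spec$seed + r - 1`.
#' @param n_replicates number of simulation-estimation replicates.
#' @param result the `calibration_result` whose typical parameters are
#'   the ground truth.
#' @param starts multi-start grid for the refit (a reduced grid by
#'   default, to keep the experiment affordable).
#' @param step,refine_step integration steps for the refit.
#' @param min_neonates minimum unexposed neonates per GA group.
#' @return A `recovery_report`: list with `errors` (per replicate x GA x
#'   parameter relative errors), `summary` (median and IQR of the
#'   relative error per parameter) and `n_replicates`.
#' @export
recovery_experiment <- function(spec = cohort_spec(),
                                n_replicates = 5L,
                                result = default_calibration(),
                                starts = NULL,
                                step = 0.05,
                                refine_step = 0.025,
                                min_neonates = 3L) {
  stopifnot(n_replicates >= 1L)
  if (is.null(starts)) {
    starts <- expand.grid(t50 = c(5, 15), hill = c(1, 2), emax_scale = 1,
                          KEEP.OUT.ATTRS = FALSE)
  }
  err_rows <- list()
  for (r in seq_len(n_replicates)) {
    spec_r <- spec
    spec_r$seed <- spec$seed + r - 1L
    cohort <- generate_cohort(spec_r, result)
    obs <- cohort$observations
    gt <- cohort$ground_truth
    keep_ids <- gt$id[!gt$exposed]
    obs <- obs[obs$id %in% keep_ids, , drop = FALSE]

    counts <- table(gt$ga_weeks[!gt$exposed])
    ga_keep <- as.numeric(names(counts)[counts >= min_neonates])
    obs <- obs[obs$ga_weeks %in% ga_keep, , drop = FALSE]
    if (length(ga_keep) < 2L)
      stop("too few unexposed gestational-age groups to refit")

    anchors <- data.frame(ga_weeks = obs$ga_weeks,
                          time_day = obs$time_day,
                          concentration_mg_dl = obs$creatinine_mg_dl)
    ga_levels <- sort(unique(anchors$ga_weeks))
    z <- anchors[anchors$time_day == 0, ]
    c0 <- tapply(z$concentration_mg_dl, z$ga_weeks, mean)
    w_tab <- tapply(obs$weight_g[!duplicated(obs$id)],
                    obs$ga_weeks[!duplicated(obs$id)], mean)
    weights_g <- as.numeric(w_tab[as.character(ga_levels)])
    names(weights_g) <- ga_levels

    fit <- calibrate_model(anchors = anchors, config = result$config,
                           weights_g = weights_g, c0 = c0,
                           starts = starts, step = step,
                           refine_step = refine_step)

    true_pars <- interpolate_parameters(result, ga_levels)
    for (g in seq_along(ga_levels)) {
      est <- fit$estimates[fit$estimates$ga_weeks == ga_levels[g], ]
      tp <- true_pars[[g]]
      for (parm in c("emax", "production_rate", "t50", "hill")) {
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          replicate = r, ga_weeks = ga_levels[g], parameter = parm,
          true = tp[[parm]], estimated = est[[parm]],
          rel_error = abs(est[[parm]] - tp[[parm]]) / abs(tp[[parm]]))
      }
    }
  }
  errors <- do.call(rbind, err_rows)
  agg <- function(f) tapply(errors$rel_error, errors$parameter, f)
  summary <- data.frame(parameter = names(agg(stats::median)),
                        median_rel_error = as.numeric(agg(stats::median)),
                        q25 = as.numeric(agg(function(x)
                          stats::quantile(x, 0.25))),
                        q75 = as.numeric(agg(function(x)
                          stats::quantile(x, 0.75))))
  structure(list(errors = errors, summary = summary,
                 n_replicates = n_replicates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicate(s)\n", x$n_replicates))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
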