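# Virtual cohort generation and simulation-estimation recovery.

quiet_spec <- function(n, seed = 11L, ...) {
  cohort_spec(n_neonates = n, seed = seed,
              bsv_cv = list(emax = 0, production_rate = 0, cl_bl = 0),
              weight_sdlog = 0, residual_prop = 0, residual_add = 0, ...)
}

test_that("cohort generation is deterministic and neonates are
           independent", {
  spec <- cohort_spec(n_neonates = 30, seed = 5L)
  a <- generate_cohort(spec, default_calibration())
  b <- generate_cohort(spec, default_calibration())
  expect_identical(a$observations, b$observations)
  expect_identical(a$ground_truth, b$ground_truth)
  # a neonate's records do not depend on how many follow it
  spec_small <- cohort_spec(n_neonates = 12, seed = 5L)
  c <- generate_cohort(spec_small, default_calibration())
  small_ids <- unique(c$observations$id)
  prefix <- a$observations[a$observations$id %in% small_ids, , drop = FALSE]
  rownames(prefix) <- NULL
  rownames(c$observations) <- NULL
  expect_identical(c$observations, prefix)
})

test_that("with noise and variability switched off every observation sits
           on the typical trajectory", {
  spec <- quiet_spec(8, exposure_fraction = 0)
  cohort <- generate_cohort(spec, default_calibration())
  obs <- cohort$observations
  for (id in unique(obs$id)) {
    rows <- obs[obs$id == id, ]
    ga <- rows$ga_weeks[1]
    params <- interpolate_parameters(default_calibration(), ga)[[1]]
    prof <- neonate_profile(id, ga, rows$weight_g[1],
                            neocreat:::typical_initial_creatinine(ga))
    traj <- simulate_concentration(prof, params, list(), 42, spec$sim_step)
    expect_equal(rows$creatinine_mg_dl,
                 trajectory_at(traj, rows$time_day), tolerance = 1e-10)
  }
  # same-GA neonates share identical parameters and weights
  gt <- cohort$ground_truth
  dup <- gt$ga_weeks[duplicated(gt$ga_weeks)]
  for (ga in unique(dup)) {
    g <- gt[gt$ga_weeks == ga, ]
    expect_equal(length(unique(g$weight_g)), 1L)
    expect_equal(length(unique(g$emax)), 1L)
  }
})

test_that("the default cohort emulates the source data set's structure", {
  spec <- cohort_spec(n_neonates = 217, seed = 3L)
  cohort <- generate_cohort(spec, default_calibration())
  n_obs <- nrow(cohort$observations)
  expect_gt(n_obs, 4026 * 0.9)
  expect_lt(n_obs, 4026 * 1.1)
  expect_true(all(cohort$observations$creatinine_mg_dl > 0))
  expect_true(all(cohort$observations$time_day >= 0 &
                    cohort$observations$time_day <= 42))
  # ground truth never leaks into the observation table
  expect_false(any(c("emax", "production_rate", "t50", "hill") %in%
                     names(cohort$observations)))
})

test_that("gestational-age and weight distributions hit the cohort
           targets at large n", {
  spec <- cohort_spec(n_neonates = 2000, seed = 17L)
  cohort <- generate_cohort(spec, default_calibration())
  gt <- cohort$ground_truth
  expect_equal(median(gt$ga_weeks), 27)
  expect_equal(as.numeric(quantile(gt$ga_weeks, c(0.25, 0.75), type = 1)),
               c(26, 28))
  expect_lt(abs(median(gt$weight_g) - 830) / 830, 0.05)
  expect_lt(abs(quantile(gt$weight_g, 0.25) - 720) / 720, 0.10)
  expect_lt(abs(quantile(gt$weight_g, 0.75) - 910) / 910, 0.10)
})

test_that("exposed neonates dominate their unexposed counterfactual
           during treatment", {
  spec <- cohort_spec(n_neonates = 20, seed = 23L, exposure_fraction = 1)
  cohort <- generate_cohort(spec, default_calibration())
  gt <- cohort$ground_truth
  expect_true(all(gt$exposed))
  i <- 1L
  params <- model_parameters(emax = gt$emax[i], t50 = gt$t50[i],
                             hill = gt$hill[i],
                             production_rate = gt$production_rate[i],
                             cl_bl_raw = gt$cl_bl_raw[i])
  prof <- neonate_profile(gt$id[i], gt$ga_weeks[i], gt$weight_g[i],
                          gt$initial_creatinine[i])
  ibu <- simulate_concentration(prof, params, list(treatment_course(1)),
                                10, 0.01)
  ctrl <- simulate_concentration(prof, params, list(), 10, 0.01)
  expect_true(all(ibu$concentration_mg_dl >= ctrl$concentration_mg_dl))
  expect_gt(trajectory_at(ibu, 3) - trajectory_at(ctrl, 3), 0)
})

test_that("a noise-free cohort returns the generating parameters", {
  spec <- quiet_spec(60, seed = 29L, exposure_fraction = 0.2)
  rep <- recovery_experiment(spec, n_replicates = 1L,
                             result = default_calibration(),
                             min_neonates = 2L)
  expect_true(all(rep$errors$rel_error < 0.01))
})
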