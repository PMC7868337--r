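# Parameter reconstruction from anchor points.

truth_anchor_set <- function(times = c(0, 3, 14, 17, 28, 31)) {
  ga <- c(24, 27, 29, 32)
  w <- c(621, 779, 840, 889)
  c0 <- c(0.383, 0.462, 0.518, 0.607)
  rows <- list()
  for (g in seq_along(ga)) {
    p <- truth_by_ga(ga[g])
    prof <- neonate_profile(paste0("GA", ga[g]), ga[g], w[g], c0[g])
    traj <- simulate_concentration(prof, p, list(), 31, 0.005)
    rows[[g]] <- data.frame(ga_weeks = ga[g], time_day = times,
                            arm = "no_ibuprofen",
                            concentration_mg_dl = trajectory_at(traj, times))
  }
  do.call(rbind, rows)
}

test_that("the packaged anchor set matches the reference tables", {
  a <- reference_anchors()
  expect_equal(nrow(a), 24L)
  expect_true(all(a$arm == "no_ibuprofen"))
  expect_setequal(unique(a$time_day), c(0, 3, 14, 17, 28, 31))
  look <- function(ga, t) a$concentration_mg_dl[a$ga_weeks == ga &
                                                  a$time_day == t]
  expect_equal(look(24, 3), 0.876)
  expect_equal(look(32, 0), 0.607)
  both <- reference_anchors("both")
  expect_equal(nrow(both), 48L)
  # before-values are arm-invariant in the packaged set
  ibu <- reference_anchors("ibuprofen")
  for (ga in c(24, 27, 29, 32)) {
    expect_equal(look(ga, 0), ibu$concentration_mg_dl[ibu$ga_weeks == ga &
                                                        ibu$time_day == 0])
    expect_equal(look(ga, 14), ibu$concentration_mg_dl[ibu$ga_weeks == ga &
                                                         ibu$time_day == 14])
  }
})

test_that("noise-free anchors from a known model are recovered", {
  anchors <- truth_anchor_set()
  fit <- calibrate_model(anchors = anchors, starts = reduced_starts(),
                         step = 0.05, refine_step = 0.01)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-8)
  for (ga in c(24, 27, 29, 32)) {
    truth <- truth_by_ga(ga)
    est <- fit$estimates[fit$estimates$ga_weeks == ga, ]
    for (parm in c("emax", "production_rate", "t50", "hill")) {
      expect_lt(abs(est[[parm]] - truth[[parm]]) / truth[[parm]], 0.01)
    }
  }
  local_cache$selffit <- fit
})

test_that("zero-width bounds pin parameters exactly and the objective is
           permutation invariant", {
  anchors <- truth_anchor_set()
  shape <- c(t50 = 13, hill = 1.39, t50_slope = -0.115,
             hill_slope = 0.013)
  bounds <- list(production_rate = c(0.1, 10), emax = c(0.01, 5),
                 t50 = c(shape[["t50"]], shape[["t50"]]),
                 hill = c(shape[["hill"]], shape[["hill"]]),
                 t50_slope = rep(shape[["t50_slope"]], 2),
                 hill_slope = rep(shape[["hill_slope"]], 2))
  fit <- calibrate_model(anchors = anchors, bounds = bounds,
                         starts = reduced_starts()[1, , drop = FALSE],
                         step = 0.05, refine_step = 0.01)
  expect_equal(fit$shape[["t50_ref"]], 13)
  expect_equal(fit$shape[["hill_ref"]], 1.39)
  expect_equal(unique(round(fit$estimates$t50 /
                              (13 * exp(-0.115 * (fit$estimates$ga_weeks - 27))),
                            10)), 1)
  # objective is a sum over anchors: order must not matter
  set.seed(7)
  shuffled <- anchors[sample(nrow(anchors)), ]
  fit2 <- calibrate_model(anchors = shuffled, bounds = bounds,
                          starts = reduced_starts()[1, , drop = FALSE],
                          step = 0.05, refine_step = 0.01)
  expect_equal(fit2$objective, fit$objective, tolerance = 1e-10)
  # objective equals the sum of squared residuals to machine precision
  expect_equal(fit$objective, sum(fit$residuals$residual^2))
})

test_that("a zero ibuprofen reduction yields exactly zero predicted
           treatment differences", {
  cfg <- default_config()
  cfg$model$ibuprofen_reduction_ml_min <- 0
  anchors <- truth_anchor_set()
  fit <- calibrate_model(anchors = anchors, config = cfg,
                         starts = reduced_starts(), step = 0.05,
                         refine_step = 0.01, consistency_band = NULL)
  expect_true(fit$converged)
  val <- validate_treatment_effect(fit, cfg)
  expect_equal(val$predicted_mg_dl, rep(0, 12))
})

test_that("calibration rejects malformed anchor sets", {
  expect_error(calibrate_model(anchors = data.frame()), "non-empty")
  a <- reference_anchors("ibuprofen")
  expect_error(calibrate_model(anchors = a), "no-ibuprofen")
  b <- reference_anchors()
  b <- b[b$time_day > 0, ]
  expect_error(calibrate_model(anchors = b), "initial")
})
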