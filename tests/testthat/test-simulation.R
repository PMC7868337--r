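# Numerical integration of the concentration dynamics.

test_that("with no production and constant clearance the solution is a
           pure exponential decay", {
  p <- fixture_params(emax = 0, production_rate = 0)
  prof <- fixture_profile()
  traj <- simulate_concentration(prof, p, t_end = 10, step = 0.005)
  k <- 0.26625 / 0.4347
  expect_lt(max(abs(traj$concentration_mg_dl -
                      prof$initial_creatinine * exp(-k * traj$time_day))),
            1e-6)
})

test_that("with constant clearance the concentration approaches
           production / clearance steady state", {
  p <- fixture_params(emax = 0, production_rate = 2.5)
  prof <- fixture_profile()
  traj <- simulate_concentration(prof, p, t_end = 42, step = 0.005)
  c_ss <- 2.5 / (10 * 0.26625)   # mg/dl: input over clearance in dl/day
  expect_lt(abs(traj$concentration_mg_dl[nrow(traj)] - c_ss), 1e-4)
})

test_that("halving the step barely changes the solution", {
  p <- fixture_params()
  prof <- fixture_profile()
  course <- treatment_course(1)
  a <- simulate_concentration(prof, p, list(course), 42, 0.005)
  b <- simulate_concentration(prof, p, list(course), 42, 0.0025)
  shared <- match(a$time_day, b$time_day)
  expect_lt(max(abs(a$concentration_mg_dl -
                      b$concentration_mg_dl[shared])), 1e-5)
})

test_that("the integrator agrees with a naive fine-step Euler oracle", {
  for (ga in c(24, 32)) {
    prof <- fixture_profile(ga, weight = c(`24` = 621, `32` = 889)[[as.character(ga)]],
                            c0 = c(`24` = 0.383, `32` = 0.607)[[as.character(ga)]])
    p <- truth_by_ga(ga)
    traj <- simulate_concentration(prof, p, list(treatment_course(1)),
                                   t_end = 14, step = 0.005)
    oracle <- euler_oracle(prof, p, window = c(0, 3), t_end = 14, h = 1e-4)
    at <- seq(0, 14, by = 0.5)
    ours <- trajectory_at(traj, at)
    theirs <- approx(oracle$times, oracle$conc, xout = at)$y
    expect_lt(max(abs(ours - theirs)), 1e-4)
  }
})

test_that("the integrator matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- fixture_params()
  prof <- fixture_profile()
  vd <- 0.4347
  rhs <- function(t, y, parms) {
    cl <- maturation_clearance(t, p)
    list(p$production_rate / (10 * vd) - cl / vd * y)
  }
  sol <- deSolve::ode(y = c(C = prof$initial_creatinine),
                      times = seq(0, 42, by = 0.5), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  traj <- simulate_concentration(prof, p, t_end = 42, step = 0.005)
  expect_lt(max(abs(trajectory_at(traj, sol[, "time"]) - sol[, "C"])),
            1e-6)
})

test_that("exposure raises the concentration from the window start on and
           leaves it untouched before", {
  prof <- fixture_profile(27, 779, 0.462)
  p <- truth_by_ga(27)
  course <- treatment_course(15)
  ctrl <- simulate_concentration(prof, p, list(), 42, 0.005)
  ibu <- simulate_concentration(prof, p, list(course), 42, 0.005)
  pre <- ctrl$time_day < 14
  expect_identical(ibu$concentration_mg_dl[pre],
                   ctrl$concentration_mg_dl[pre])
  post <- ctrl$time_day > 14
  expect_true(all(ibu$concentration_mg_dl[post] >=
                    ctrl$concentration_mg_dl[post]))
  expect_true(all(ibu$concentration_mg_dl > 0))
  expect_true(all(ibu$clearance_l_day > 0))
})

test_that("exposure flags and the clearance channel follow the window", {
  prof <- fixture_profile()
  p <- fixture_params()
  course <- treatment_course(15, 3)
  traj <- simulate_concentration(prof, p, list(course), 42, 0.01)
  expect_identical(traj$exposed,
                   traj$time_day >= 14 - 1e-9 & traj$time_day <= 17 + 1e-9)
  inside <- traj$exposed
  expect_equal(traj$clearance_l_day[inside],
               maturation_clearance(traj$time_day[inside], p) - 0.013536)
  expect_equal(traj$clearance_l_day[!inside],
               maturation_clearance(traj$time_day[!inside], p))
})

test_that("simulation rejects invalid grids and overlapping courses", {
  prof <- fixture_profile()
  p <- fixture_params()
  expect_error(simulate_concentration(prof, p, step = 0.1), "0.05")
  expect_error(simulate_concentration(prof, p, t_end = -1), "positive")
  expect_error(
    simulate_concentration(prof, p,
                           list(treatment_course(1), treatment_course(3)),
                           42, 0.005),
    "overlap")
  # windows must sit on the integration grid
  expect_error(simulate_concentration(prof, p, list(treatment_course(2)),
                                      42, 0.035), "multiples")
})
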