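# Shared fixtures and independent oracles for the test suite.

# A plausible parameter set for module-level tests (close to, but not
# dependent on, the calibrated values).
fixture_params <- function(emax = 0.8, t50 = 13, hill = 1.4,
                           production_rate = 2.9, ...) {
  model_parameters(emax = emax, t50 = t50, hill = hill,
                   production_rate = production_rate, ...)
}

fixture_profile <- function(ga = 24, weight = 621, c0 = 0.383) {
  neonate_profile(paste0("GA", ga), ga, weight, c0)
}

# Ground-truth parameter set for self-consistency experiments, expressed
# through the same GA-covariate structure the calibration fits.
truth_by_ga <- function(ga) {
  t50 <- 13 * exp(-0.115 * (ga - 27))
  hill <- 1.39 * exp(0.013 * (ga - 27))
  emax <- approx(c(24, 27, 29, 32), c(0.80, 0.78, 0.75, 0.71),
                 xout = ga, rule = 2)$y
  prod <- approx(c(24, 27, 29, 32), c(2.91, 2.91, 2.90, 2.88),
                 xout = ga, rule = 2)$y
  model_parameters(emax = emax, t50 = t50, hill = hill,
                   production_rate = prod)
}

# Independent brute-force oracle: naive forward-Euler integration of
# dC/dt = production/Vd_dl - CL_adj(t)/Vd * C with its own clearance
# arithmetic (no calls into the package's integrator).
euler_oracle <- function(profile, params, window = NULL, t_end = 42,
                         h = 1e-4) {
  vd_l <- params$vd_per_kg * profile$birth_weight / 1000
  u <- params$production_rate / (10 * vd_l)
  cl_bl <- params$cl_bl_raw * params$baseline_covariate_factor
  n <- round(t_end / h)
  conc <- numeric(n + 1L)
  conc[1L] <- profile$initial_creatinine
  t <- 0
  for (i in seq_len(n)) {
    cl <- cl_bl + params$emax * t^params$hill /
      (params$t50^params$hill + t^params$hill)
    if (!is.null(window) && t >= window[1] - 1e-12 &&
        t < window[2] - 1e-12) {
      cl <- max(cl - params$ibuprofen_reduction, params$clearance_floor)
    }
    conc[i + 1L] <- conc[i] + h * (u - cl / vd_l * conc[i])
    t <- t + h
  }
  list(times = seq(0, by = h, length.out = n + 1L), conc = conc)
}

# Cached expensive fits, shared across test files within one session.
local_cache <- new.env(parent = emptyenv())

reduced_starts <- function() {
  expand.grid(t50 = c(5, 15), hill = c(1, 2), emax_scale = 1,
              KEEP.OUT.ATTRS = FALSE)
}
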