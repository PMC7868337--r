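#' Maturing creatinine clearance
#'
#' Postnatal creatinine clearance follows a sigmoid Emax (Hill) function of
#' postnatal age: `CL(t) = CL_bl + emax * t^hill / (t50^hill + t^hill)`,
#' where `CL_bl` is the effective baseline clearance
#' (`cl_bl_raw * baseline_covariate_factor`). The function is monotone
#' non-decreasing in `t` and bounded by `CL_bl + emax`.
#'
#' @param t postnatal age, days (vectorised; must be >= 0).
#' @param params a [model_parameters()] object.
#' @return Clearance in L/day, same length as `t`.
#' @export
#' @examples
#' p <- model_parameters(emax = 0.4, t50 = 10, hill = 2,
#'                       production_rate = 2)
#' maturation_clearance(0, p)   # 0.26625
#' maturation_clearance(10, p)  # 0.26625 + 0.2
maturation_clearance <- function(t, params) {
  stopifnot(is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("postnatal age t must be finite and >= 0")
  frac <- hill_fraction(t, params$t50, params$hill)
  baseline_clearance(params) + params$emax * frac
}

# t^h / (t50^h + t^h), computed on the log scale for numerical safety.
hill_fraction <- function(t, t50, hill) {
  frac <- numeric(length(t))
  pos <- t > 0
  r <- exp(hill * (log(t[pos]) - log(t50)))
  frac[pos] <- r / (1 + r)
  frac
}

#' Creatinine distribution volume
#'
#' `Vd = vd_per_kg * weight`, with weight converted from grams to kg.
#'
#' @param weight body weight, grams (> 0, vectorised).
#' @param params a [model_parameters()] object.
#' @return Volume in litres.
#' @export
#' @examples
#' p <- model_parameters(emax = 0.4, t50 = 10, hill = 2, production_rate = 2)
#' distribution_volume(621, p) # 0.4347 L
distribution_volume <- function(weight, params) {
  stopifnot(is.numeric(weight))
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be finite and > 0 g")
  params$vd_per_kg * weight / 1000
}

#' Ibuprofen effect on clearance
#'
#' While an ibuprofen course is active, clearance is reduced by a constant
#' absolute amount (`ibuprofen_reduction`, reference value 0.0094 ml/min =
#' 0.013536 L/day) — identical at every postnatal age and gestational age —
#' and floored at `clearance_floor` to preserve positivity. Unexposed
#' clearance is returned unchanged.
#'
#' @param cl clearance, L/day (> 0, vectorised).
#' @param exposed logical, recycled against `cl`.
#' @param params a [model_parameters()] object.
#' @return Adjusted clearance, L/day.
#' @export
apply_ibuprofen_effect <- function(cl, exposed, params) {
  stopifnot(is.numeric(cl), is.logical(exposed))
  if (any(!is.finite(cl)) || any(cl <= 0)) stop("cl must be > 0")
  exposed <- rep_len(exposed, length(cl))
  ifelse(exposed, pmax(cl - params$ibuprofen_reduction,
                       params$clearance_floor), cl)
}

#' Creatinine elimination rate constant
#'
#' `ket(t) = CL_adjusted(t) / Vd`, the first-order removal rate of
#' creatinine, where `CL_adjusted` is the maturing clearance after any
#' ibuprofen adjustment and `Vd` the distribution volume at birth weight.
#'
#' @param t postnatal age, days (vectorised).
#' @param profile a [neonate_profile()].
#' @param params a [model_parameters()] object.
#' @param exposed logical: is an ibuprofen course active at `t`?
#' @return Elimination rate in 1/day.
#' @export
elimination_rate <- function(t, profile, params, exposed = FALSE) {
  cl <- apply_ibuprofen_effect(maturation_clearance(t, params),
                               exposed, params)
  cl / distribution_volume(profile$birth_weight, params)
}

# ---------------------------------------------------------------------------
# Fixed-step classical RK4 for the linear turnover ODE
#   dC/dt = u - k(t) * C           (C in mg/dl, u in mg/dl/day, k in 1/day)
# vectorised over m units sharing one time grid. `k_stage` holds k at the
# 2*n_steps + 1 stage times (grid points and midpoints); `kred_step` is an
# optional per-step rate reduction (ibuprofen), applied to all stages of a
# step so that exposure switches exactly at grid points.
rk4_linear <- function(c0, u, k_stage, h, kred_step = NULL,
                       k_floor = NULL) {
  m <- length(c0)
  n_steps <- (nrow(k_stage) - 1L) %/% 2L
  out <- matrix(NA_real_, n_steps + 1L, m)
  out[1L, ] <- c0
  conc <- c0
  if (is.null(k_floor)) k_floor <- rep(1e-12, m)
  reduce <- !is.null(kred_step)
  for (i in seq_len(n_steps)) {
    ka <- k_stage[2L * i - 1L, ]
    kb <- k_stage[2L * i, ]
    kc <- k_stage[2L * i + 1L, ]
    if (reduce) {
      r <- kred_step[i, ]
      ka <- pmax(ka - r, k_floor)
      kb <- pmax(kb - r, k_floor)
      kc <- pmax(kc - r, k_floor)
    }
    s1 <- u - ka * conc
    s2 <- u - kb * (conc + 0.5 * h * s1)
    s3 <- u - kb * (conc + 0.5 * h * s2)
    s4 <- u - kc * (conc + h * s3)
    conc <- conc + h / 6 * (s1 + 2 * s2 + 2 * s3 + s4)
    out[i + 1L, ] <- conc
  }
  out
}

check_courses <- function(courses, step, t_end) {
  if (inherits(courses, "treatment_course")) courses <- list(courses)
  if (length(courses) == 0L) return(list())
  windows <- t(vapply(courses, course_window, numeric(2)))
  ord <- order(windows[, 1L])
  windows <- windows[ord, , drop = FALSE]
  if (any(windows[-1L, 1L] < windows[-nrow(windows), 2L] - 1e-9))
    stop("treatment courses overlap")
  for (w in as.numeric(windows)) {
    if (abs(w / step - round(w / step)) > 1e-6)
      stop("treatment window endpoints must be multiples of the step")
  }
  courses[ord]
}

#' Simulate a serum creatinine trajectory
#'
#' Integrates the one-compartment creatinine balance
#' `dC/dt = production_rate / Vd_dl - ket(t) * C` (C in mg/dl; `Vd_dl` the
#' distribution volume in decilitres) on a uniform grid with a classical
#' 4th-order fixed-step Runge-Kutta scheme. The clearance maturation
#' function is evaluated at the Runge-Kutta stage times; ibuprofen exposure
#' switches exactly at grid points, and course window endpoints must be
#' multiples of the step.
#'
#' @param profile a [neonate_profile()].
#' @param params a [model_parameters()] object.
#' @param courses a list of non-overlapping [treatment_course()] objects
#'   (possibly empty).
#' @param t_end simulation horizon, days (default 42).
#' @param step integration step, days; must satisfy `0 < step <= 0.05`
#'   (accuracy guard).
#' @return A `creatinine_trajectory`: a data frame with columns `time_day`,
#'   `concentration_mg_dl`, `clearance_l_day` (post-adjustment) and
#'   `exposed` (logical), with the profile, parameters and courses attached
#'   as attributes.
#' @export
#' @examples
#' prof <- neonate_profile("GA24", 24, 621, 0.383)
#' pars <- model_parameters(emax = 0.55, t50 = 16, hill = 1.4,
#'                          production_rate = 2.5)
#' traj <- simulate_concentration(prof, pars,
#'                                courses = list(treatment_course(1)),
#'                                t_end = 7)
#' head(traj)
simulate_concentration <- function(profile, params, courses = list(),
                                   t_end = 42, step = 0.005) {
  stopifnot(inherits(profile, "neonate_profile"),
            inherits(params, "model_parameters"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("t_end must be a positive scalar")
  if (!is.numeric(step) || length(step) != 1L || step <= 0 ||
      step > 0.05 + 1e-12)
    stop("step must satisfy 0 < step <= 0.05 day")
  n_steps <- round(t_end / step)
  if (abs(n_steps * step - t_end) > 1e-8)
    stop("t_end must be a multiple of step")
  courses <- check_courses(courses, step, t_end)

  times <- seq(0, by = step, length.out = n_steps + 1L)
  stage_times <- seq(0, by = step / 2, length.out = 2L * n_steps + 1L)
  vd_l <- distribution_volume(profile$birth_weight, params)
  k_stage <- matrix(maturation_clearance(stage_times, params) / vd_l,
                    ncol = 1L)
  u <- params$production_rate / (10 * vd_l)

  exposed_grid <- rep(FALSE, n_steps + 1L)
  kred_step <- NULL
  if (length(courses)) {
    kred <- rep(0, n_steps)
    t_lo <- times[-length(times)]
    t_hi <- times[-1L]
    for (course in courses) {
      w <- course_window(course)
      exposed_grid <- exposed_grid |
        (times >= w["start"] - 1e-9 & times <= w["end"] + 1e-9)
      inside <- t_lo >= w["start"] - 1e-9 & t_hi <= w["end"] + 1e-9
      kred[inside] <- params$ibuprofen_reduction / vd_l
    }
    kred_step <- matrix(kred, ncol = 1L)
  }

  conc <- rk4_linear(c0 = profile$initial_creatinine, u = u,
                     k_stage = k_stage, h = step, kred_step = kred_step,
                     k_floor = params$clearance_floor / vd_l)
  cl_grid <- apply_ibuprofen_effect(maturation_clearance(times, params),
                                    exposed_grid, params)
  traj <- data.frame(time_day = times,
                     concentration_mg_dl = conc[, 1L],
                     clearance_l_day = cl_grid,
                     exposed = exposed_grid)
  structure(traj,
            class = c("creatinine_trajectory", "data.frame"),
            profile = profile, params = params, courses = courses,
            step = step)
}

#' Look up a trajectory value at given times
#'
#' Linear interpolation of a simulated trajectory channel at arbitrary
#' times inside the simulated horizon.
#'
#' @param traj a trajectory from [simulate_concentration()].
#' @param t times, days.
#' @param channel `"concentration_mg_dl"` or `"clearance_l_day"`.
#' @return Numeric vector of interpolated values.
#' @export
trajectory_at <- function(traj, t, channel = "concentration_mg_dl") {
  stopifnot(channel %in% c("concentration_mg_dl", "clearance_l_day"))
  if (any(t < min(traj$time_day) - 1e-9 | t > max(traj$time_day) + 1e-9))
    stop("requested time outside the simulated horizon")
  stats::approx(traj$time_day, traj[[channel]], xout = t, rule = 2)$y
}
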