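#' Hill 1938 hyperbolic force-velocity parameters
#'
#' The hyperbola \eqn{(T_a + a) v = b (T_a^{iso} - T_a)} in normalized
#' form (velocity in 1/s after division by fiber length).
#'
#' @param a_over_Tiso dimensionless curvature parameter \eqn{a /
#'   T_a^{iso}}.
#' @param b normalized rate constant, 1/s.
#' @param T_iso_kPa isometric tension, kPa.
#' @return An object of class \code{"hill_params"}.
#' @export
hill_params <- function(a_over_Tiso = 0.22, b = 0.27, T_iso_kPa = 120) {
  stopifnot(a_over_Tiso > 0, b >= 0, T_iso_kPa > 0)
  structure(list(a_over_Tiso = a_over_Tiso, b = b, T_iso_kPa = T_iso_kPa),
            class = "hill_params")
}

#' Hill hyperbola tension at a given velocity
#'
#' Solves \eqn{(T_a + a) v = b (T_a^{iso} - T_a)} for \eqn{T_a}:
#' \eqn{T_a = (b T_a^{iso} - a v) / (b + v)}.
#'
#' @param v normalized shortening velocity(ies), 1/s, nonnegative.
#' @param p a [hill_params()].
#' @return tension(s), kPa.
#' @export
hill_tension <- function(v, p) {
  stopifnot(inherits(p, "hill_params"), all(v >= 0))
  a <- p$a_over_Tiso * p$T_iso_kPa
  (p$b * p$T_iso_kPa - a * v) / (p$b + v)
}

#' Maximum shortening velocity of the Hill hyperbola
#'
#' \eqn{v^{max} = b T_a^{iso} / a = b / (a/T_a^{iso})}.
#'
#' @param p a [hill_params()].
#' @return velocity, 1/s.
#' @examples
#' hill_vmax(hill_params(a_over_Tiso = 0.22, b = 0.27105))  # 1.23 1/s
#' @export
hill_vmax <- function(p) {
  stopifnot(inherits(p, "hill_params"))
  p$b / p$a_over_Tiso
}

#' Normalize a fiber velocity by fiber length
#'
#' Fiber-level rate constants (e.g. Hill's b) divided by the fiber
#' length give length-independent normalized rates. Arguments carry
#' explicit units to prevent cm/mm mix-ups.
#'
#' @param v_fiber_mm_per_s fiber velocity, mm/s.
#' @param L_fiber_mm fiber length, mm, positive.
#' @return normalized velocity, 1/s.
#' @examples
#' normalize_fiber_velocity(10.3, 38)  # Hill's b_fiber = 1.03 cm/s, 38 mm
#' @export
normalize_fiber_velocity <- function(v_fiber_mm_per_s, L_fiber_mm) {
  if (any(L_fiber_mm <= 0)) stop("fiber length must be positive")
  v_fiber_mm_per_s / L_fiber_mm
}

#' Steady force-velocity sweep
#'
#' Evaluates the steady normalized tension on a velocity grid using the
#' model's own destruction law (so a sublinear model is swept with
#' \eqn{q = \alpha\sqrt{|v|}}). For linear growth the curve coincides
#' with the [normalized_force_velocity()] closed form.
#'
#' @param m an [xb_model()].
#' @param v velocity grid, 1/s; defaults to 60 points spanning the zero
#'   crossing.
#' @return data.frame with columns \code{v_per_s}, \code{T_norm},
#'   \code{T_kPa}.
#' @export
run_force_velocity <- function(m, v = NULL) {
  predict(m, v = v, type = "force_velocity")
}

#' Quick-release length-step experiment
#'
#' Lets the model sit at the isometric steady state, applies the
#' rectangular velocity pulse of a [step_protocol()], and follows the
#' tension recovery. The trace is assembled from the exact
#' constant-velocity solution on each segment, so the end-of-step value
#' equals [end_of_step_tension()] to machine precision and the
#' post-step recovery toward the isometric tension is governed by
#' \eqn{r_0}.
#'
#' @param m an [xb_model()].
#' @param step a [step_protocol()].
#' @param t_end trace end time, s.
#' @param n_out number of output samples.
#' @return data.frame with columns \code{t_s}, \code{T_Pa},
#'   \code{T_norm}.
#' @export
run_length_step <- function(m, step, t_end = 0.1, n_out = 400L) {
  stopifnot(inherits(m, "xb_model"), inherits(step, "step_protocol"),
            t_end > step$delta_t)
  vbar <- step$delta_L / step$delta_t
  s0 <- steady_moments(m, 0)
  T_iso <- s0$T_Pa
  t1 <- seq(0, step$delta_t, length.out = max(8L, ceiling(n_out / 8)))
  ph1 <- analytic_constant_v(m, vbar, t1, init = c(s0$mu0, s0$mu1))
  endst <- c(ph1$mu0[nrow(ph1)], ph1$mu1[nrow(ph1)])
  t2 <- seq(0, t_end - step$delta_t, length.out = n_out)
  ph2 <- analytic_constant_v(m, 0, t2, init = endst)
  out <- data.frame(
    t_s = c(ph1$t, step$delta_t + ph2$t[-1]),
    T_Pa = c(ph1$T_Pa, ph2$T_Pa[-1]))
  out$T_norm <- out$T_Pa / T_iso
  out
}

#' Generate a seeded synthetic measurement dataset
#'
#' Virtual laboratory data for parameter-recovery studies: a
#' force-velocity sweep (absolute tension, kPa) and a quick-release
#' series (normalized end-of-step tension at a stored step duration),
#' both with additive i.i.d. Gaussian noise of standard deviation
#' \code{sigma} on the normalized tension scale, plus one noisy
#' isometric attached-fraction reading. Deterministic given
#' \code{seed}; the caller's RNG state is left untouched.
#'
#' @param m an [xb_model()].
#' @param sigma noise s.d. on normalized tension, nonnegative.
#' @param n_fv number of force-velocity points (grid spans v = 0 to 20%
#'   past the simulated zero crossing).
#' @param n_step number of step points on \eqn{\Delta L \in [0,
#'   0.06]}.
#' @param seed integer seed.
#' @param delta_t step duration used for the step series, s. The small
#'   default characterizes the fast (T2) response.
#' @return An object of class \code{"xb_dataset"}: list with data
#'   frames \code{fv} (\code{v_per_s}, \code{T_kPa}) and \code{steps}
#'   (\code{delta_L}, \code{T_norm}, \code{delta_t_s}), scalar
#'   \code{mu0_iso}, plus \code{seed} and \code{sigma}.
#' @export
generate_noisy_measurements <- function(m, sigma = 0.02, n_fv = 50L,
                                        n_step = 25L, seed = 1L,
                                        delta_t = 1e-6) {
  stopifnot(inherits(m, "xb_model"), sigma >= 0, n_fv >= 5, n_step >= 5)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  vz <- simulated_vmax(m)
  if (is.na(vz)) stop("model has no zero crossing; cannot span v_max")
  vgrid <- seq(0, 1.2 * vz, length.out = n_fv)
  T_iso <- steady_moments(m, 0)$T_Pa
  T_norm <- steady_moments(m, vgrid)$T_Pa / T_iso
  fv <- data.frame(
    v_per_s = vgrid,
    T_kPa = (T_norm + stats::rnorm(n_fv, sd = sigma)) * T_iso / 1e3)

  dL <- seq(0, 0.06, length.out = n_step)
  st_norm <- end_of_step_tension(m, dL, delta_t = delta_t) / T_iso
  steps <- data.frame(
    delta_L = dL,
    T_norm = st_norm + stats::rnorm(n_step, sd = sigma),
    delta_t_s = delta_t)

  mu0 <- m$P * m$mu_f0 / m$r0
  mu0_meas <- mu0 * (1 + stats::rnorm(1, sd = sigma))

  structure(list(fv = fv, steps = steps, mu0_iso = mu0_meas,
                 seed = seed, sigma = sigma),
            class = "xb_dataset")
}

#' @export
print.xb_dataset <- function(x, ...) {
  cat("Synthetic crossbridge dataset: ", nrow(x$fv),
      " force-velocity points, ", nrow(x$steps),
      " length-step points (sigma = ", x$sigma,
      ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Recover measured quantities from a synthetic dataset
#'
#' Operationalizes calibration from curve data. Local polynomial fits
#' provide starting values (isometric intercept and stall slope from a
#' quadratic fit on the 5 smallest velocities, the zero crossing by
#' linear interpolation, the step stiffness from a linear fit on
#' \eqn{\Delta L \le 0.01}); these are then refined by
#' Levenberg-Marquardt fits of the closed-form families — the
#' linear-growth normalized force-velocity curve for
#' (\eqn{T_a^{iso}, r_0, \alpha, \mu_f^0/\mu_f^1}) and the exact
#' end-of-step tension at the dataset's step duration for
#' \eqn{\tilde k_2}. With \code{sigma = 0} and linear-growth data the
#' recovery is exact.
#'
#' @param d an \code{"xb_dataset"}.
#' @return an [measured_quantities()] estimate.
#' @export
recover_measurements <- function(d) {
  stopifnot(inherits(d, "xb_dataset"))
  fv <- d$fv
  if (min(fv$v_per_s) > 0) stop("dataset must include v = 0")
  if (all(fv$T_kPa > 0)) stop("zero crossing not bracketed by the dataset")

  # --- starting values from local fits
  small <- order(abs(fv$v_per_s))[1:5]
  qf <- stats::lm(T_kPa ~ v_per_s + I(v_per_s^2), data = fv[small, ])
  T0 <- unname(stats::coef(qf)[1])
  slope <- unname(stats::coef(qf)[2])
  v0_start <- max(-T0 / slope, 1e-3)
  ic <- which(diff(sign(fv$T_kPa)) < 0)[1]
  vmax_start <- fv$v_per_s[ic] - fv$T_kPa[ic] *
    (fv$v_per_s[ic + 1] - fv$v_per_s[ic]) /
    (fv$T_kPa[ic + 1] - fv$T_kPa[ic])
  st_small <- d$steps[d$steps$delta_L <= 0.01, ]
  lf <- stats::lm(T_norm ~ delta_L, data = st_small)
  k2_start <- max(-unname(stats::coef(lf)[2]), 2 / vmax_start * 1.01)
  r0_start <- k2_start * v0_start
  alpha_start <- k2_start / 2 * max(1 - v0_start / vmax_start, 0.05)
  m_start <- k2_start - alpha_start

  # --- force-velocity family in its identifiable parameterization
  # T(v) = Tiso * (1/(1+Av) - M v / (1+Av)^2) with A = alpha/r0, M = m/r0;
  # the curve determines only these ratios (v_max = 1/(M-A), v0 = 1/(M+A))
  fv_model <- function(p, v) {
    den <- 1 + p[2] * v
    p[1] * (1 / den - p[3] * v / den^2)
  }
  res_fv <- function(p) fv_model(p, fv$v_per_s) - fv$T_kPa
  fit_fv <- minpack.lm::nls.lm(
    par = c(T0, alpha_start / r0_start, m_start / r0_start), fn = res_fv,
    lower = c(1e-6, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  pf <- fit_fv$par
  T_iso_hat <- pf[1]; A_hat <- pf[2]; M_hat <- pf[3]
  v_max_hat <- if (M_hat > A_hat) 1 / (M_hat - A_hat) else NA_real_
  v0_hat <- 1 / (M_hat + A_hat)

  # --- step family: normalized end-of-step tension, linear q, known delta.
  # The force-velocity fit fixes the ratios A = alpha/r0 and M = m/r0, so
  # the step curve identifies the single remaining rate scale r0, and
  # k2 = alpha + m = (A + M) * r0.
  delta <- d$steps$delta_t_s[1]
  step_norm <- function(r0, dL) {
    alpha <- A_hat * r0; mm <- M_hat * r0
    vbar <- dL / delta
    r <- r0 + alpha * vbar
    e <- exp(-r * delta)
    r0 * (1 / r0 + ((1 / r - 1 / r0) - mm * vbar / r^2) * (1 - e) +
            mm * (1 / r - 1 / r0) * dL * e)
  }
  res_st <- function(p) step_norm(p[1], d$steps$delta_L) - d$steps$T_norm
  fit_st <- minpack.lm::nls.lm(
    par = c(k2_start * v0_hat), fn = res_st, lower = 1e-6,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  k2_hat <- (A_hat + M_hat) * fit_st$par[1]

  measured_quantities(T_iso_kPa = T_iso_hat, mu0_iso = d$mu0_iso,
                      v_max = v_max_hat, v0 = v0_hat, k2 = k2_hat)
}
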