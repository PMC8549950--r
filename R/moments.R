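#' Piecewise-constant velocity schedule
#'
#' Right-continuous step function: \code{values[i]} holds on
#' \code{[times[i], times[i+1])}, the last value from \code{times[k]}
#' onward. Used for quick-release protocols, where the rectangular pulse
#' \eqn{v(t) = (\Delta L/\delta) 1_{[0,\delta]}(t)} is
#' \code{v_schedule(c(0, delta), c(delta_L/delta, 0))}.
#'
#' @param times breakpoints, s, nondecreasing, starting at 0.
#' @param values velocity on each interval (same length as
#'   \code{times}).
#' @return An object of class \code{"v_schedule"}.
#' @export
v_schedule <- function(times, values) {
  stopifnot(length(times) == length(values), times[1] == 0,
            !is.unsorted(times))
  structure(list(times = times, values = values), class = "v_schedule")
}

v_schedule_eval <- function(s, t) {
  idx <- findInterval(t, s$times, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  s$values[idx]
}

#' Integrate the two-moment reduction numerically
#'
#' Solves the exact moment ODEs
#' \deqn{\dot\mu^0 = -r(v)\mu^0 + P \mu_f^0, \qquad
#'       \dot\mu^1 = -r(v)\mu^1 + P \mu_f^1 - \mu^0 v,}
#' with \eqn{r(v) = r_0 + q(v)}, using adaptive stiff-capable stepping
#' (lsoda, absolute/relative tolerances 1e-10). Piecewise-constant
#' schedules are integrated segment by segment so that velocity jumps
#' never cross an internal step.
#'
#' @param m an [xb_model()].
#' @param v normalized velocity, 1/s: scalar, function of time, or
#'   [v_schedule()].
#' @param t_end final time, s.
#' @param init initial moments, numeric \code{c(mu0, mu1)}; defaults to
#'   the isometric steady state.
#' @param times output times, s.
#' @return data.frame with columns \code{t}, \code{mu0}, \code{mu1},
#'   \code{T_Pa} (\eqn{a_{XB}\mu^1}).
#' @seealso [analytic_constant_v()] for the constant-velocity closed
#'   form this is verified against.
#' @export
solve_moments <- function(m, v, t_end, init = NULL, times = NULL) {
  stopifnot(inherits(m, "xb_model"), t_end > 0)
  if (is.null(init)) {
    s <- steady_moments(m, 0)
    init <- c(s$mu0, s$mu1)
  }
  stopifnot(length(init) == 2L)
  if (is.null(times)) times <- seq(0, t_end, length.out = 101L)
  times <- sort(unique(c(0, times[times <= t_end + 1e-15], t_end)))

  rhs <- function(t, y, parms, vv) {
    r <- xb_total_rate(m, vv)
    list(c(-r * y[1] + m$P * m$mu_f0,
           -r * y[2] + m$P * m$mu_f1 - y[1] * vv))
  }

  if (inherits(v, "v_schedule")) {
    brk <- unique(c(v$times[v$times < t_end], t_end))
    y <- init
    res <- matrix(NA_real_, nrow = length(times), ncol = 2L)
    res[1, ] <- init
    for (i in seq_len(length(brk) - 1L)) {
      t0 <- brk[i]; t1 <- brk[i + 1L]
      if (t1 <= t0) next
      vv <- v_schedule_eval(v, t0)
      tt <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
      sol <- deSolve::lsoda(y, tt, rhs, parms = NULL, vv = vv,
                            rtol = 1e-10, atol = 1e-10)
      keep <- tt %in% times
      res[match(tt[keep], times), ] <- sol[keep, 2:3]
      y <- as.numeric(sol[nrow(sol), 2:3])
    }
  } else {
    vfun <- as_velocity_function(v)
    rhs_t <- function(t, y, parms) rhs(t, y, parms, vfun(t))
    sol <- deSolve::lsoda(init, times, rhs_t, parms = NULL,
                          rtol = 1e-10, atol = 1e-10)
    res <- sol[, 2:3, drop = FALSE]
  }
  data.frame(t = times, mu0 = res[, 1], mu1 = res[, 2],
             T_Pa = m$a_XB * res[, 2])
}

#' Steady-state moments at constant velocity
#'
#' Closed form
#' \deqn{\bar\mu^0 = P\mu_f^0/r(v), \qquad
#'       \bar\mu^1 = P(\mu_f^1/r(v) - \mu_f^0 v / r(v)^2).}
#' The active tension is \eqn{T_a = a_{XB}\bar\mu^1}.
#'
#' @param m an [xb_model()].
#' @param v normalized velocity(ies), 1/s.
#' @return list with vectors \code{mu0}, \code{mu1}, \code{T_Pa}.
#' @export
steady_moments <- function(m, v) {
  stopifnot(inherits(m, "xb_model"))
  r <- xb_total_rate(m, v)
  mu0 <- m$P * m$mu_f0 / r
  mu1 <- m$P * (m$mu_f1 / r - m$mu_f0 * v / r^2)
  list(mu0 = mu0, mu1 = mu1, T_Pa = m$a_XB * mu1)
}

#' Constant-velocity analytic moment solution
#'
#' Exact solution of the two-moment system for constant \eqn{v}:
#' \deqn{\mu^0(t) = \bar\mu^0 + (\mu^0(0) - \bar\mu^0) e^{-r t},}
#' \deqn{\mu^1(t) = \bar\mu^1 + (\mu^1(0) - \bar\mu^1) e^{-r t}
#'       + (\bar\mu^0 - \mu^0(0))\, v\, t\, e^{-r t},}
#' with \eqn{r = r(v)} and the steady values of [steady_moments()]. The
#' resonant \eqn{t e^{-rt}} term arises because the \eqn{\mu^0}
#' transient forces \eqn{\mu^1} at its own decay rate.
#'
#' @param m an [xb_model()].
#' @param v constant normalized velocity, 1/s.
#' @param t time(s), s.
#' @param init initial moments \code{c(mu0, mu1)}; defaults to the
#'   isometric steady state.
#' @return data.frame with columns \code{t}, \code{mu0}, \code{mu1},
#'   \code{T_Pa}.
#' @export
analytic_constant_v <- function(m, v, t, init = NULL) {
  stopifnot(inherits(m, "xb_model"), all(t >= 0))
  if (is.null(init)) {
    s0 <- steady_moments(m, 0)
    init <- c(s0$mu0, s0$mu1)
  }
  r <- xb_total_rate(m, v)
  s <- steady_moments(m, v)
  dec <- exp(-r * t)
  mu0 <- s$mu0 + (init[1] - s$mu0) * dec
  mu1 <- s$mu1 + (init[2] - s$mu1) * dec + (s$mu0 - init[1]) * v * t * dec
  data.frame(t = t, mu0 = mu0, mu1 = mu1, T_Pa = m$a_XB * mu1)
}

#' Tension at the end of a rapid length step
#'
#' Exact end-of-step active tension for the rectangular velocity pulse
#' \eqn{v = \Delta L/\delta} on \eqn{[0, \delta]}, starting from the
#' isometric steady state:
#' \deqn{T_a(\delta) = a_{XB} P \left[\frac{\mu_f^1}{r_0}
#'  + \left(\mu_f^1\left(\frac{1}{r} - \frac{1}{r_0}\right)
#'          - \frac{\mu_f^0}{r^2}\frac{\Delta L}{\delta}\right)
#'    (1 - e^{-r\delta})
#'  + \mu_f^0\left(\frac{1}{r} - \frac{1}{r_0}\right)
#'    \Delta L\, e^{-r\delta}\right],}
#' with \eqn{r = r(\Delta L/\delta)}.
#'
#' @param m an [xb_model()].
#' @param step a [step_protocol()], or a numeric vector of
#'   \code{delta_L} values combined with \code{delta_t}.
#' @param delta_t step duration, s, used when \code{step} is numeric.
#' @return tension(s), Pa.
#' @seealso [asymptotic_step_tension()] for the instantaneous-step
#'   limit.
#' @export
end_of_step_tension <- function(m, step, delta_t = 200e-6) {
  stopifnot(inherits(m, "xb_model"))
  if (inherits(step, "step_protocol")) {
    dL <- step$delta_L; dt <- step$delta_t
  } else {
    dL <- step; dt <- delta_t
  }
  stopifnot(dt > 0)
  vbar <- dL / dt
  r <- xb_total_rate(m, vbar)
  e <- exp(-r * dt)
  T_iso_term <- m$mu_f1 / m$r0
  m$a_XB * m$P * (T_iso_term +
    (m$mu_f1 * (1 / r - 1 / m$r0) - m$mu_f0 / r^2 * vbar) * (1 - e) +
    m$mu_f0 * (1 / r - 1 / m$r0) * dL * e)
}

#' Instantaneous-step tension asymptote
#'
#' Limit of the end-of-step tension as the step duration vanishes,
#' depending only on the growth class of the destruction term:
#' \describe{
#'   \item{sublinear (or bounded)}{\eqn{T_a \to a_{XB}P(\mu_f^1 -
#'     \mu_f^0 \Delta L)/r_0}: a linear-elastic line.}
#'   \item{linear}{\eqn{T_a \to a_{XB}P e^{-\alpha\Delta L}(\mu_f^1 -
#'     \mu_f^0 \Delta L)/r_0}.}
#'   \item{superlinear}{\eqn{T_a \to 0}: an instantaneous step destroys
#'     every crossbridge.}
#' }
#'
#' @param m an [xb_model()].
#' @param delta_L dimensionless shortening(s).
#' @return tension(s), Pa.
#' @export
asymptotic_step_tension <- function(m, delta_L) {
  stopifnot(inherits(m, "xb_model"))
  base <- m$a_XB * m$P * (m$mu_f1 - m$mu_f0 * delta_L) / m$r0
  switch(m$growth,
    sublinear = base,
    linear = exp(-m$alpha * delta_L) * base,
    superlinear = rep(0, length(delta_L)),
    stop("unknown growth kind: ", m$growth))
}

#' Normalized force-velocity closed form
#'
#' The steady normalized tension under the small-velocity (linear)
#' destruction law \eqn{q(v) = \alpha|v|}:
#' \deqn{\frac{T_a}{T_a^{iso}} = \frac{1}{1 + \alpha|v|/r_0}
#'  - \frac{\mu_f^0/\mu_f^1}{(1 + \alpha|v|/r_0)^2}\frac{v}{r_0}.}
#' Equals 1 at \eqn{v = 0}, crosses zero at
#' \eqn{v^{max} = r_0(\mu_f^0/\mu_f^1 - \alpha)^{-1}}, and is
#' independent of the permissivity and of the tension scale. With
#' \eqn{\alpha = 0} it reduces to the straight line of the classic
#' model. For a sublinear-growth model this is the curve implied by its
#' small-velocity coefficient, not the one simulated with
#' \eqn{q = \alpha\sqrt{|v|}}; see [run_force_velocity()].
#'
#' @param m an [xb_model()].
#' @param v normalized velocity(ies), 1/s.
#' @return dimensionless tension(s).
#' @export
normalized_force_velocity <- function(m, v) {
  stopifnot(inherits(m, "xb_model"))
  d <- 1 + m$alpha * abs(v) / m$r0
  1 / d - (m$mu_f0 / m$mu_f1) / d^2 * v / m$r0
}

#' Characteristic macroscopic quantities of a model
#'
#' Forward closed forms mapping model parameters to the five calibration
#' observables:
#' \deqn{T_a^{iso} = a_{XB} P \mu_f^1 / r_0, \quad
#'       \mu^0_{iso} = P \mu_f^0 / r_0,}
#' \deqn{v^{max} = r_0 (\mu_f^0/\mu_f^1 - \alpha)^{-1}, \quad
#'       v^0 = r_0 (\mu_f^0/\mu_f^1 + \alpha)^{-1},}
#' and the fast-step stiffness \eqn{\tilde k_2 = \mu_f^0/\mu_f^1}
#' (sublinear growth) or \eqn{\mu_f^0/\mu_f^1 + \alpha} (linear growth;
#' also used for superlinear models, whose calibration reuses the linear
#' relations). When \eqn{\alpha \ge \mu_f^0/\mu_f^1} in the linear case
#' the force-velocity curve never crosses zero and \code{v_max} is
#' returned as \code{NA} with a warning.
#'
#' @param m an [xb_model()].
#' @return an [measured_quantities()] object.
#' @export
characteristic_quantities <- function(m) {
  stopifnot(inherits(m, "xb_model"))
  ratio <- m$mu_f0 / m$mu_f1
  v_max <- if (m$alpha >= ratio) {
    warning("alpha >= mu_f0/mu_f1: v_max is undefined")
    NA_real_
  } else m$r0 / (ratio - m$alpha)
  measured_quantities(
    T_iso_kPa = m$a_XB * m$P * m$mu_f1 / m$r0 / 1e3,
    mu0_iso = m$P * m$mu_f0 / m$r0,
    v_max = v_max,
    v0 = m$r0 / (ratio + m$alpha),
    k2 = if (m$growth == "sublinear") ratio else ratio + m$alpha)
}
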