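#' Uniform displacement grid for the transport-reaction solver
#'
#' @param x_min,x_max domain bounds, nm; must straddle zero and contain
#'   the support of the attachment rate strictly inside.
#' @param n_points number of nodes.
#' @return An object of class \code{"xb_grid"} with fields \code{x},
#'   \code{dx}, \code{n_points}.
#' @export
xb_grid <- function(x_min = -40, x_max = 25, n_points = 1300) {
  stopifnot(x_min < 0, x_max > 0, n_points >= 3)
  x <- seq(x_min, x_max, length.out = n_points)
  structure(list(x = x, dx = x[2] - x[1], n_points = n_points,
                 x_min = x_min, x_max = x_max),
            class = "xb_grid")
}

#' Solve the two-state sliding-filament transport-reaction equation
#'
#' Integrates
#' \deqn{\partial_t n - v_{hs}(t) \partial_x n = (P - n) f(x) - n g(x)}
#' on a uniform grid with zero-inflow boundaries. Advection uses
#' first-order upwinding along the characteristic direction (CFL number
#' 0.9); because the reaction is linear in \eqn{n} it is integrated
#' exactly per step via the exponential update
#' \eqn{n \to n_\infty + (n - n_\infty) e^{-(f+g)\Delta t}} with
#' \eqn{n_\infty = P f / (f+g)}, which keeps the scheme stable for
#' arbitrarily fast detachment and preserves \eqn{0 \le n \le P}.
#'
#' @param f,g vectorized rate functions of displacement x (nm) returning
#'   1/s; evaluated once on the grid (they may close over a velocity if
#'   the destruction term is wanted: the solver treats them as frozen in
#'   x).
#' @param v_hs half-sarcomere shortening velocity, nm/s: a scalar, a
#'   function of time, or a [v_schedule()] (values interpreted in nm/s).
#'   Positive values shorten (convect the distribution toward negative
#'   x).
#' @param t_end final time, s.
#' @param grid an [xb_grid()].
#' @param P permissivity in (0, 1].
#' @param n_init initial nodal values (defaults to zero), within
#'   \code{[0, P]}.
#' @param times output times; defaults to 50 equally spaced points.
#' @param dt_max optional cap on the step size, s.
#' @return An object of class \code{"xb_pde"}: list with \code{x} (nm),
#'   \code{times} (s), \code{n} (matrix, one row per output time),
#'   \code{P}.
#' @seealso [analytic_huxley_steady()] for the constant-velocity oracle,
#'   [force_from_distribution()].
#' @export
solve_h57 <- function(f, g, v_hs, t_end, grid = xb_grid(), P = 1,
                      n_init = NULL, times = NULL, dt_max = Inf) {
  stopifnot(inherits(grid, "xb_grid"), t_end > 0, P > 0, P <= 1)
  x <- grid$x
  fx <- f(x); gx <- g(x)
  if (any(fx < 0) || any(gx < 0)) stop("rates must be nonnegative")
  vfun <- as_velocity_function(v_hs)
  if (is.null(n_init)) n_init <- numeric(length(x))
  if (length(n_init) != length(x)) stop("n_init must match the grid")
  if (any(n_init < 0) || any(n_init > P))
    stop("initial state out of bounds [0, P]")
  if (is.null(times)) times <- seq(0, t_end, length.out = 51L)
  times <- sort(unique(c(0, times[times <= t_end + 1e-15], t_end)))

  # step size from the CFL condition on the largest speed encountered
  vprobe <- abs(vfun(seq(0, t_end, length.out = 1001L)))
  vmax <- max(vprobe)
  cfl <- 0.9
  dt <- if (vmax > 0) cfl * grid$dx / vmax else t_end / 200
  dt <- min(dt, dt_max, t_end / 50)

  rate <- fx + gx
  n <- n_init
  out <- matrix(0, nrow = length(times), ncol = length(x))
  out[1, ] <- n
  t_now <- 0
  k_out <- 2L
  while (k_out <= length(times)) {
    t_target <- times[k_out]
    while (t_now < t_target - 1e-15) {
      step <- min(dt, t_target - t_now)
      v_now <- vfun(t_now)
      if (abs(v_now) * step > grid$dx)  # guard when a partial step was larger
        step <- grid$dx / abs(v_now) * cfl
      # upwind advection of n_t = v_hs n_x (profile moves toward -x for v>0)
      if (v_now > 0) {
        nu <- v_now * step / grid$dx
        n <- n + nu * (c(n[-1], 0) - n)
      } else if (v_now < 0) {
        nu <- -v_now * step / grid$dx
        n <- n + nu * (c(0, n[-length(n)]) - n)
      }
      # exact reaction update
      dec <- exp(-rate * step)
      ninf <- ifelse(rate > 0, P * fx / rate, 0)
      n <- ninf + (n - ninf) * dec
      t_now <- t_now + step
    }
    out[k_out, ] <- n
    k_out <- k_out + 1L
  }
  structure(list(x = x, times = times, n = out, P = P, grid = grid),
            class = "xb_pde")
}

#' @export
print.xb_pde <- function(x, ...) {
  cat("Two-state distribution trajectory:", length(x$times), "snapshots on",
      length(x$x), "nodes, t in [0,", format(max(x$times)), "] s\n")
  invisible(x)
}

# coerce scalar / function / v_schedule into a function of time
as_velocity_function <- function(v) {
  if (inherits(v, "v_schedule")) {
    return(function(t) v_schedule_eval(v, t))
  }
  if (is.function(v)) return(v)
  if (is.numeric(v) && length(v) == 1L) return(function(t) rep(v, length(t)))
  stop("velocity must be a scalar, a function of time, or a v_schedule")
}

#' Analytic steady distribution of the classic Huxley model
#'
#' The constant-velocity steady-state profile
#' \deqn{n(x) = F_1 (1 - e^{-\varphi/v_{hs}})
#'              e^{x g_2 / v_{hs}}, \quad x < 0,}
#' \deqn{n(x) = F_1 (1 - e^{(x^2/h^2 - 1)\varphi/v_{hs}}),
#'       \quad 0 \le x < h,}
#' and zero for \eqn{x \ge h}. The negative-branch decay rate
#' \eqn{g_2/v_{hs}} (equivalently \eqn{(2/h) G_2 \varphi / v_{hs}}) is
#' what the transport equation demands for pure detachment at rate
#' \eqn{g_2} under leftward convection, and is the form consistent with
#' the closed-form force-velocity relation (its \eqn{v^2/g_2^2} term is
#' the first moment of this exponential tail). For \code{v_hs = 0} the
#' pointwise isometric limit \eqn{n = F_1} on \eqn{[0, h)}, zero
#' elsewhere, is returned.
#'
#' @param x displacement(s), nm.
#' @param v_hs constant shortening velocity, nm/s, nonnegative.
#' @param p a [huxley_rate_params()].
#' @return attached probability in \eqn{[0, F_1]}.
#' @export
analytic_huxley_steady <- function(x, v_hs, p) {
  stopifnot(inherits(p, "huxley_rate_params"), v_hs >= 0)
  if (v_hs == 0) {
    return(ifelse(x >= 0 & x < p$h, p$F1, 0))
  }
  r <- p$phi / v_hs
  ifelse(x >= p$h, 0,
    ifelse(x >= 0,
      p$F1 * (1 - exp((x^2 / p$h^2 - 1) * r)),
      p$F1 * (1 - exp(-r)) * exp(x * p$g2 / v_hs)))
}

#' Closed-form Huxley force-velocity relation
#'
#' Steady-state force per half-filament pair at constant shortening
#' velocity:
#' \deqn{F_{hf} = \rho_{AM} k_{XB} F_1 \frac{h^2}{2}
#'   \left(1 - \frac{v}{\varphi}(1 - e^{-\varphi/v})
#'   \left(1 + \frac{1}{2 G_2^2}\frac{v}{\varphi}\right)\right).}
#'
#' @param v_hs shortening velocity(ies), nm/s, nonnegative.
#' @param p a [huxley_rate_params()].
#' @param fp a [filament_force_params()].
#' @return force, pN (for rho_AM in 1/nm and k_XB in pN/nm).
#' @export
huxley_force_velocity <- function(v_hs, p, fp = filament_force_params()) {
  stopifnot(inherits(p, "huxley_rate_params"),
            inherits(fp, "filament_force_params"), all(v_hs >= 0))
  scale <- fp$rho_AM * fp$k_XB * p$F1 * p$h^2 / 2
  u <- v_hs / p$phi
  bracket <- ifelse(u == 0, 1,
    1 - u * (1 - exp(-1 / u)) * (1 + u / (2 * p$G2^2)))
  scale * bracket
}

#' Maximum shortening velocity of the classic Huxley model
#'
#' Positive root of the closed-form force-velocity relation, located by
#' bracketed root finding (relative tolerance 1e-12). For the classic
#' fit (F1 = 13/16, G2 = 3.919) the root sits at approximately four
#' times the rate constant \eqn{\varphi = (f_1+g_1)h/2}.
#'
#' @param p a [huxley_rate_params()].
#' @return velocity, nm/s.
#' @examples
#' huxley_vmax(huxley_rate_params(65, 15, 313.5, 10))  # ~1600 nm/s
#' @export
huxley_vmax <- function(p) {
  stopifnot(inherits(p, "huxley_rate_params"))
  fv <- function(v) 1 - (v / p$phi) * (1 - exp(-p$phi / v)) *
    (1 + v / (2 * p$G2^2 * p$phi))
  lo <- 1e-6 * p$phi
  hi <- 2 * p$phi
  while (fv(hi) > 0 && hi < 1e6 * p$phi) hi <- hi * 2
  if (fv(hi) > 0) stop("no sign change found: force-velocity curve ",
                       "does not cross zero")
  stats::uniroot(fv, c(lo, hi), tol = 1e-12 * p$phi)$root
}

#' Force from a gridded distribution
#'
#' Trapezoidal evaluation of
#' \eqn{F_{hf} = \rho_{AM} k_{XB} \int x\, n(x) dx}.
#'
#' @param state either an \code{"xb_pde"} trajectory (the last snapshot
#'   is used unless \code{i} is given) or a list with fields \code{x}
#'   and \code{n} (vector).
#' @param fp a [filament_force_params()].
#' @param i snapshot index for a trajectory.
#' @return force, pN.
#' @export
force_from_distribution <- function(state, fp = filament_force_params(),
                                    i = NULL) {
  if (inherits(state, "xb_pde")) {
    if (is.null(i)) i <- nrow(state$n)
    x <- state$x; n <- state$n[i, ]
  } else {
    x <- state$x; n <- state$n
  }
  fp$rho_AM * fp$k_XB * trapz(x, x * n)
}

# trapezoid rule on a (possibly nonuniform) grid
trapz <- function(x, y) {
  m <- length(x)
  sum((y[-1] + y[-m]) * diff(x)) / 2
}

#' Normalized distribution moments on the grid
#'
#' Evaluates \eqn{\mu^p = \int (x/(SL_0/2))^p n(x) dx / D_M} for each
#' stored snapshot of a PDE trajectory; the same normalization used by
#' the moment ODE reduction, enabling direct cross-checks.
#'
#' @param traj an \code{"xb_pde"} object.
#' @param p moment order.
#' @param SL0,D_M geometry, nm.
#' @return numeric vector, one value per snapshot.
#' @export
pde_moments <- function(traj, p = 0, SL0 = 2200, D_M = 43) {
  stopifnot(inherits(traj, "xb_pde"))
  w <- (traj$x / (SL0 / 2))^p
  apply(traj$n, 1, function(n) trapz(traj$x, w * n)) / D_M
}
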