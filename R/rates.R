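#' Huxley attachment rate
#'
#' The linear-ramp attachment rate \eqn{f(x) = f_1 (x/h)} on the closed
#' interval \eqn{[0, h]}, zero elsewhere. Attachment only at positive
#' displacement is the symmetry-breaking feature that makes the filament
#' pair contract.
#'
#' @param x displacement(s), nm.
#' @param p a [huxley_rate_params()].
#' @return attachment rate(s), 1/s.
#' @export
huxley_f <- function(x, p) {
  stopifnot(inherits(p, "huxley_rate_params"))
  ifelse(x >= 0 & x <= p$h, p$f1 * x / p$h, 0)
}

#' Huxley detachment rate
#'
#' \eqn{g(x) = g_2} for \eqn{x \le 0} and \eqn{g_1 (x/h)} for
#' \eqn{x > 0}. The large \eqn{g_2} prevents crossbridges from resisting
#' contraction at negative displacement.
#'
#' @inheritParams huxley_f
#' @return detachment rate(s), 1/s.
#' @export
huxley_g <- function(x, p) {
  stopifnot(inherits(p, "huxley_rate_params"))
  ifelse(x <= 0, p$g2, p$g1 * x / p$h)
}

#' Velocity-destruction rate q(v)
#'
#' Evaluates the destruction term for a given growth class; see
#' [q_spec()]. Even in \code{v}, zero at \code{v = 0}.
#'
#' @param v normalized velocity(ies), 1/s.
#' @param q a [q_spec()].
#' @return rate(s), 1/s.
#' @examples
#' q_of_v(2, q_spec(24.37, "linear"))    # 48.74
#' q_of_v(4, q_spec(39, "sublinear"))    # 78
#' @export
q_of_v <- function(v, q) {
  stopifnot(inherits(q, "q_spec"))
  av <- abs(v)
  switch(q$growth,
    sublinear   = q$alpha * sqrt(av),
    linear      = q$alpha * av,
    superlinear = q$alpha * (av + av^2),
    stop("unknown growth kind: ", q$growth))
}

#' Window attachment/detachment rates
#'
#' The constant-window rate family: attachment at \code{k_ATP} inside
#' \eqn{[s_0, s_0+h]}, detachment at \code{k_ATP} outside plus the
#' velocity-destruction term. By construction
#' \eqn{f(x,v) + g(x,v) = k_{ATP} + q(v)} for every \eqn{x}.
#'
#' @param x displacement(s), nm.
#' @param v normalized velocity, 1/s.
#' @param p a [micro_window_params()].
#' @return a list with vectors \code{f} and \code{g} (1/s).
#' @export
window_rates <- function(x, v, p) {
  stopifnot(inherits(p, "micro_window_params"))
  inside <- x >= p$s0 & x <= p$s0 + p$h
  f <- ifelse(inside, p$k_ATP, 0)
  g <- ifelse(inside, 0, p$k_ATP) + q_of_v(v, p$q)
  list(f = f, g = g)
}

#' Window rates to moment-level parameters
#'
#' Closed-form attachment-rate moments of the window family:
#' \deqn{\mu_f^0 = k_{ATP} h / D_M, \quad
#'       \mu_f^1 = k_{ATP} h (h + 2 s_0) / (SL_0 D_M), \quad
#'       r_0 = k_{ATP}.}
#' The destruction spec is passed through unchanged. The tension scale
#' \code{a_XB} is not determined by the microscopic description and must
#' be supplied.
#'
#' @param p a [micro_window_params()].
#' @param a_XB tension scale, Pa.
#' @param P permissivity.
#' @return an [xb_model()].
#' @export
micro_to_moment <- function(p, a_XB = 1e6, P = 1) {
  stopifnot(inherits(p, "micro_window_params"))
  xb_model(
    mu_f0 = p$k_ATP * p$h / p$D_M,
    mu_f1 = p$k_ATP * p$h * (p$h + 2 * p$s0) / (p$SL0 * p$D_M),
    r0 = p$k_ATP,
    alpha = p$q$alpha, growth = p$q$growth,
    a_XB = a_XB, P = P, SL0 = p$SL0, D_M = p$D_M)
}

#' Moment-level parameters to window rates
#'
#' Inverse of [micro_to_moment()], giving a microscopic interpretation to
#' the moment-level constants:
#' \deqn{k_{ATP} = r_0, \quad h = \mu_f^0 D_M / k_{ATP}, \quad
#'       s_0 = (SL_0 \mu_f^1 / \mu_f^0 - h) / 2.}
#' Exact roundtrip with the forward map.
#'
#' @param m an [xb_model()].
#' @param D_M,SL0 filament geometry, nm; default to the values stored in
#'   \code{m}.
#' @return a [micro_window_params()].
#' @export
moment_to_micro <- function(m, D_M = m$D_M, SL0 = m$SL0) {
  stopifnot(inherits(m, "xb_model"))
  k_ATP <- m$r0
  h <- m$mu_f0 * D_M / k_ATP
  if (h <= 0) stop("non-positive window width h implied by parameters")
  s0 <- (SL0 * m$mu_f1 / m$mu_f0 - h) / 2
  micro_window_params(k_ATP = k_ATP, s0 = s0, h = h, D_M = D_M, SL0 = SL0,
                      q = m$q)
}

#' Normalized moments of an attachment-rate function
#'
#' Computes \eqn{\mu_f^p = \int (x / (SL_0/2))^p f(x) dx / D_M} by
#' adaptive quadrature. The rate function must have bounded support
#' contained in \code{[lower, upper]}.
#'
#' @param f a vectorized function of displacement x (nm) returning rates
#'   (1/s).
#' @param p moment order (nonnegative integer).
#' @param SL0 reference sarcomere length, nm.
#' @param D_M myosin spacing, nm.
#' @param lower,upper integration bounds, nm.
#' @return the moment, 1/s.
#' @export
moments_of_f <- function(f, p = 0, SL0 = 2200, D_M = 43,
                         lower = -100, upper = 100) {
  stopifnot(is.function(f), p >= 0, p == round(p), lower < upper)
  integrand <- function(x) (x / (SL0 / 2))^p * f(x)
  val <- stats::integrate(integrand, lower, upper,
                          rel.tol = 1e-10, abs.tol = 1e-12,
                          subdivisions = 2000L, stop.on.error = FALSE)
  if (!val$message %in% c("OK", "roundoff error was detected"))
    stop("quadrature failed: ", val$message)
  val$value / D_M
}

# total transition rate r(v) = r0 + q(v) for a moment-level model
xb_total_rate <- function(m, v) m$r0 + q_of_v(v, m$q)
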