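#' Velocity-dependent crossbridge destruction term
#'
#' Specifies the extra detachment rate \eqn{q(v)} incurred under rapid
#' filament sliding. Three growth classes are supported:
#' \describe{
#'   \item{sublinear}{\eqn{q(v) = \alpha \sqrt{|v|}}}
#'   \item{linear}{\eqn{q(v) = \alpha |v|}}
#'   \item{superlinear}{\eqn{q(v) = \alpha (|v| + v^2)}}
#' }
#' All are even in \eqn{v}, nonnegative, and vanish at \eqn{v = 0}.
#' The growth class controls the instantaneous response to fast length
#' steps: sublinear growth yields a linear-elastic end-of-step line,
#' linear growth an exponentially damped one, and superlinear growth
#' destroys all crossbridges in the limit of an instantaneous step.
#'
#' @param alpha nonnegative coefficient. Dimensionless for linear growth
#'   (the normalized velocity \eqn{v} carries 1/s); for the other classes
#'   it absorbs the corresponding fractional power of time.
#' @param growth one of \code{"sublinear"}, \code{"linear"},
#'   \code{"superlinear"}.
#' @return An object of class \code{"q_spec"}.
#' @seealso [q_of_v()]
#' @export
q_spec <- function(alpha, growth = c("sublinear", "linear", "superlinear")) {
  growth <- match.arg(growth)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0)
  structure(list(alpha = alpha, growth = growth), class = "q_spec")
}

#' @export
print.q_spec <- function(x, ...) {
  form <- switch(x$growth,
    sublinear = "alpha * sqrt(|v|)",
    linear = "alpha * |v|",
    superlinear = "alpha * (|v| + v^2)")
  cat("q(v) = ", form, ",  alpha = ", format(x$alpha), "\n", sep = "")
  invisible(x)
}

#' Classic Huxley two-state rate constants
#'
#' Container for the 1957 attachment/detachment rate laws
#' \eqn{f(x) = f_1 x/h} on \eqn{[0, h]} and
#' \eqn{g(x) = g_2} for \eqn{x \le 0}, \eqn{g_1 x/h} for \eqn{x > 0}.
#' The derived constants \eqn{F_1 = f_1/(f_1+g_1)},
#' \eqn{G_2 = g_2/(f_1+g_1)} and \eqn{\varphi = (f_1+g_1) h / 2}
#' are stored alongside.
#'
#' @param f1,g1,g2 rate constants, 1/s, strictly positive.
#' @param h attachment window width, nm, strictly positive.
#' @return An object of class \code{"huxley_rate_params"} with fields
#'   \code{f1}, \code{g1}, \code{g2}, \code{h}, \code{F1}, \code{G2},
#'   \code{phi} (nm/s).
#' @examples
#' p <- huxley_rate_params(f1 = 65, g1 = 15, g2 = 313.5, h = 10)
#' p$F1   # 13/16
#' p$phi  # 400 nm/s
#' @export
huxley_rate_params <- function(f1, g1, g2, h) {
  vals <- c(f1 = f1, g1 = g1, g2 = g2, h = h)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals > 0))
  structure(list(
    f1 = f1, g1 = g1, g2 = g2, h = h,
    F1 = f1 / (f1 + g1),
    G2 = g2 / (f1 + g1),
    phi = (f1 + g1) * h / 2
  ), class = "huxley_rate_params")
}

#' @export
print.huxley_rate_params <- function(x, ...) {
  cat("Huxley two-state rates: f1 =", x$f1, "1/s, g1 =", x$g1,
      "1/s, g2 =", x$g2, "1/s, h =", x$h, "nm\n")
  cat("  F1 =", format(x$F1), " G2 =", format(x$G2),
      " phi =", format(x$phi), "nm/s\n")
  invisible(x)
}

#' Microscopic window-rate parameters
#'
#' Describes the constant-attachment-window rate family: attachment at rate
#' \code{k_ATP} for \eqn{x \in [s_0, s_0 + h]}, detachment at rate
#' \code{k_ATP} outside the window plus the velocity-destruction term
#' \eqn{q(v)}. The total transition rate \eqn{f + g = k_{ATP} + q(v)} is
#' independent of \eqn{x}, which is what makes the two-moment reduction
#' exact for this family.
#'
#' @param k_ATP ATP turnover rate, 1/s.
#' @param s0 window offset, nm (may be zero or negative).
#' @param h window width, nm, positive.
#' @param D_M spacing between consecutive myosin heads along the thick
#'   filament, nm. Default 43.
#' @param SL0 reference sarcomere length, nm. Default 2200.
#' @param q a [q_spec()].
#' @return An object of class \code{"micro_window_params"}.
#' @seealso [window_rates()], [micro_to_moment()]
#' @export
micro_window_params <- function(k_ATP, s0, h, D_M = 43, SL0 = 2200,
                                q = q_spec(0, "linear")) {
  stopifnot(is.numeric(k_ATP), k_ATP > 0, is.numeric(s0),
            is.numeric(h), h > 0, is.numeric(D_M), D_M > 0,
            is.numeric(SL0), SL0 > 0, inherits(q, "q_spec"))
  structure(list(k_ATP = k_ATP, s0 = s0, h = h, D_M = D_M, SL0 = SL0, q = q),
            class = "micro_window_params")
}

#' Generalized two-state crossbridge model
#'
#' The moment-level parameter vector of the generalized sliding-filament
#' model: attachment-moment rates \eqn{\mu_f^0}, \eqn{\mu_f^1}, isometric
#' total rate \eqn{r_0}, destruction term \eqn{q(v)} with coefficient
#' \code{alpha} and a growth class, and the tension upscaling constant
#' \eqn{a_{XB}} mapping the first distribution moment to macroscopic
#' active stress via \eqn{T_a = a_{XB} \mu^1}.
#'
#' Objects of this class are usually produced by [xb_calibrate()]; the
#' constructor is exported for direct parameter studies and for loading
#' parameter documents.
#'
#' @param mu_f0 zeroth attachment-rate moment, 1/s, positive.
#' @param mu_f1 first attachment-rate moment, 1/s, positive.
#' @param r0 isometric total transition rate \eqn{r(0)}, 1/s, positive.
#' @param alpha destruction coefficient, nonnegative.
#' @param growth growth class of \eqn{q(v)}; see [q_spec()].
#' @param a_XB tension scale, Pa, positive.
#' @param P permissivity (fraction of available binding sites), in (0, 1].
#' @param SL0 reference sarcomere length, nm.
#' @param D_M myosin head spacing, nm.
#' @return An object of class \code{"xb_model"}.
#' @examples
#' m <- xb_model(mu_f0 = 28.60, mu_f1 = 0.7040, r0 = 130,
#'               alpha = 24.375, growth = "linear", a_XB = 22.16e6)
#' summary(m)
#' @export
xb_model <- function(mu_f0, mu_f1, r0, alpha = 0,
                     growth = c("linear", "sublinear", "superlinear"),
                     a_XB = 1e6, P = 1, SL0 = 2200, D_M = 43) {
  growth <- match.arg(growth)
  stopifnot(is.numeric(mu_f0), mu_f0 > 0, is.numeric(mu_f1), mu_f1 > 0,
            is.numeric(r0), r0 > 0, is.numeric(a_XB), a_XB > 0,
            is.numeric(P), P > 0, P <= 1,
            is.numeric(SL0), SL0 > 0, is.numeric(D_M), D_M > 0)
  q <- q_spec(alpha, growth)
  if (growth == "linear" && alpha >= mu_f0 / mu_f1)
    warning("alpha >= mu_f0/mu_f1 with linear growth: ",
            "v_max is undefined (force-velocity curve never crosses zero)")
  structure(list(
    mu_f0 = mu_f0, mu_f1 = mu_f1, r0 = r0, alpha = alpha,
    growth = growth, q = q, a_XB = a_XB, P = P, SL0 = SL0, D_M = D_M,
    calibration = NULL
  ), class = "xb_model")
}

#' Macroscopic measured quantities for calibration
#'
#' The five observables from which the generalized two-state model is
#' identified: the isometric active tension, the isometric attached
#' fraction, the maximum shortening velocity (zero-tension intercept of
#' the force-velocity curve), the inverse normalized force-velocity
#' sensitivity at stall, and the normalized fast-step (T2) stiffness.
#'
#' @param T_iso_kPa isometric tension, kPa.
#' @param mu0_iso isometric attached crossbridge fraction, dimensionless.
#' @param v_max maximum normalized shortening velocity, 1/s (may be
#'   \code{NA} when undefined).
#' @param v0 inverse normalized force-velocity slope at v = 0, 1/s.
#' @param k2 normalized fast-step stiffness (T2 stiffness), dimensionless.
#' @return An object of class \code{"xb_measurements"}.
#' @examples
#' # Intact rat cardiac cell at room temperature
#' meas <- measured_quantities(T_iso_kPa = 120, mu0_iso = 0.22,
#'                             v_max = 8, v0 = 2, k2 = 66)
#' @export
measured_quantities <- function(T_iso_kPa, mu0_iso, v_max, v0, k2) {
  stopifnot(is.numeric(T_iso_kPa), T_iso_kPa > 0,
            is.numeric(mu0_iso), mu0_iso > 0,
            is.numeric(v0), v0 > 0, is.numeric(k2), k2 > 0)
  if (!is.na(v_max)) {
    stopifnot(is.numeric(v_max), v_max > 0)
    # v0 == v_max is the degenerate alpha = 0 case (classic linear
    # force-velocity); v0 > v_max is inconsistent with a convex curve
    if (v0 > v_max)
      stop("v0 must not exceed v_max (the force-velocity curve is convex)")
  }
  structure(list(T_iso_kPa = T_iso_kPa, mu0_iso = mu0_iso,
                 v_max = v_max, v0 = v0, k2 = k2),
            class = "xb_measurements")
}

#' @export
print.xb_measurements <- function(x, ...) {
  cat("Macroscopic crossbridge measurements:\n")
  cat(sprintf("  T_a^iso  %10.4g kPa\n", x$T_iso_kPa))
  cat(sprintf("  mu0_iso  %10.4g\n", x$mu0_iso))
  cat(sprintf("  v_max    %10.4g 1/s\n", x$v_max))
  cat(sprintf("  v0       %10.4g 1/s\n", x$v0))
  cat(sprintf("  k2~      %10.4g\n", x$k2))
  invisible(x)
}

#' Quick-release length-step protocol
#'
#' A relative shortening \code{delta_L} of the half sarcomere applied over
#' a duration \code{delta_t}, i.e. a rectangular velocity pulse
#' \eqn{v(t) = (\Delta L / \delta) 1_{[0,\delta]}(t)}. Positive
#' \code{delta_L} is release (tension drop).
#'
#' @param delta_L dimensionless shortening of the half sarcomere.
#' @param delta_t step duration, s, positive.
#' @return An object of class \code{"step_protocol"}.
#' @export
step_protocol <- function(delta_L, delta_t = 200e-6) {
  stopifnot(is.numeric(delta_L), length(delta_L) == 1L,
            is.numeric(delta_t), delta_t > 0)
  structure(list(delta_L = delta_L, delta_t = delta_t), class = "step_protocol")
}

#' Filament-level force constants
#'
#' @param rho_AM line density of actin-myosin pairs along the filament,
#'   1/nm.
#' @param k_XB single-crossbridge stiffness, pN/nm (of the order of 2).
#' @return An object of class \code{"filament_force_params"}.
#' @export
filament_force_params <- function(rho_AM = 1, k_XB = 2) {
  stopifnot(rho_AM > 0, k_XB > 0)
  structure(list(rho_AM = rho_AM, k_XB = k_XB), class = "filament_force_params")
}
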