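#' Soft-spin energy landscape
#'
#' Composite myosin-head energy \eqn{w_\omega(z, y) = u_\omega(y) +
#' u_e(z + y)}: an internal (power-stroke angle) energy \eqn{u_0} or
#' \eqn{u_1} depending on the attachment state, plus the elastic arm
#' energy \eqn{u_e} of the total arm elongation. For attached heads the
#' tip is pinned to the binding site, \eqn{z \equiv x}, so the attached
#' energy is \eqn{w_1(x, y) = u_1(y) + u_e(x + y)}. All energies must
#' grow unboundedly so that Boltzmann factors are integrable.
#'
#' @param u0,u1 internal-variable energy functions of y (nm), zJ, for
#'   the detached / attached state.
#' @param u_e elastic energy function of total arm elongation (nm), zJ.
#' @return An object of class \code{"xb_landscape"}.
#' @export
energy_landscape <- function(u0, u1, u_e) {
  stopifnot(is.function(u0), is.function(u1), is.function(u_e))
  structure(list(u0 = u0, u1 = u1, u_e = u_e), class = "xb_landscape")
}

#' Packaged toy landscape
#'
#' A synthetic test landscape (no measured energy surface is bundled):
#' quadratic arm elasticity \eqn{u_e(s) = k_e s^2 / 2} and a double-well
#' quartic internal energy with wells at \eqn{y = 0} (pre power stroke)
#' and \eqn{y = y_a} (post power stroke), tilted so the post-stroke well
#' is favoured when attached and penalized when detached.
#'
#' @param k_e arm stiffness, pN/nm (zJ/nm^2).
#' @param E_b barrier scale, zJ.
#' @param y_a power-stroke length, nm.
#' @param tilt energy bias per unit y, zJ/nm.
#' @return an [energy_landscape()].
#' @export
toy_landscape <- function(k_e = 2, E_b = 4, y_a = 8, tilt = 0.6) {
  dw <- function(y) E_b * (((y - y_a / 2) / (y_a / 2))^2 - 1)^2
  energy_landscape(
    u0 = function(y) dw(y) + tilt * y,
    u1 = function(y) dw(y) - tilt * y,
    u_e = function(s) k_e * s^2 / 2)
}

#' Thermal parameters
#'
#' @param kBT thermal energy, zJ (about 4.1 at room temperature).
#' @return An object of class \code{"thermal_params"}.
#' @export
thermal_params <- function(kBT = 4.1) {
  stopifnot(kBT > 0)
  structure(list(kBT = kBT), class = "thermal_params")
}

#' Detached-state Boltzmann equilibrium density
#'
#' \deqn{p_0^{th}(z, y) = e^{-w_0(z,y)/k_B T} /
#'       \int\!\!\int e^{-w_0/k_B T}\, dz\, dy}
#' evaluated on a tensor grid and normalized by the 2-D trapezoid rule.
#' A constant shift of the landscape leaves the density unchanged (the
#' minimum is subtracted before exponentiating).
#'
#' @param E an [energy_landscape()].
#' @param th a [thermal_params()].
#' @param z,y grid vectors, nm. Must extend far enough that the
#'   truncated tail mass is negligible; a warning is issued when the
#'   boundary density exceeds 1e-10 of the peak.
#' @return list with \code{z}, \code{y}, \code{p} (matrix, z by y),
#'   \code{w} (energy matrix, zJ).
#' @export
equilibrium_density_detached <- function(E, th, z, y) {
  stopifnot(inherits(E, "xb_landscape"), inherits(th, "thermal_params"))
  w <- outer(z, y, function(zz, yy) E$u0(yy) + E$u_e(zz + yy))
  b <- exp(-(w - min(w)) / th$kBT)
  edge <- max(b[1, ], b[nrow(b), ], b[, 1], b[, ncol(b)])
  if (edge > 1e-10)
    warning("Boltzmann factor not negligible at the grid boundary; ",
            "enlarge the z/y window")
  Z <- trapz2(z, y, b)
  if (!is.finite(Z) || Z <= 0) stop("non-integrable landscape on this grid")
  list(z = z, y = y, p = b / Z, w = w)
}

#' Attached-state Boltzmann equilibrium density
#'
#' One-dimensional conditional density over the power-stroke variable,
#' \eqn{p_1^{th}(y; x) \propto e^{-w_1(x,y)/k_B T}}, for an attached
#' head at displacement \code{x}.
#'
#' @inheritParams equilibrium_density_detached
#' @param x attachment displacement, nm.
#' @return list with \code{y}, \code{p} (vector), \code{w}.
#' @export
equilibrium_density_attached <- function(E, th, x, y) {
  stopifnot(inherits(E, "xb_landscape"), inherits(th, "thermal_params"))
  w <- E$u1(y) + E$u_e(x + y)
  b <- exp(-(w - min(w)) / th$kBT)
  if (max(b[1], b[length(b)]) > 1e-10)
    warning("Boltzmann factor not negligible at the grid boundary; ",
            "enlarge the y window")
  Z <- trapz(y, b)
  if (!is.finite(Z) || Z <= 0) stop("non-integrable landscape on this grid")
  list(y = y, p = b / Z, w = w)
}

#' Effective two-state rates from a soft-spin landscape
#'
#' Reduces microscopic attachment/detachment kinetics to effective
#' displacement-dependent two-state rates by averaging over the thermal
#' equilibrium of the internal degrees of freedom:
#' \deqn{f^{th}(x) = \int\!\!\int k_+(z, y, x)\, p_0^{th}(z, y)\, dz\,
#'       dy, \qquad
#'       g^{th}(x) = \int k_-(y, x)\, p_1^{th}(y; x)\, dy.}
#' Constant microscopic rates pass through unchanged; with the
#' power-stroke variable frozen at \eqn{y = 0} the reduction returns
#' \eqn{g^{th}(x) = k_-(0, x)}, recovering the classic two-state
#' picture.
#'
#' @param kplus attachment rate function \code{(z, y, x)}, vectorized
#'   in z and y, 1/s.
#' @param kminus detachment rate function \code{(y, x)}, vectorized in
#'   y, 1/s.
#' @param E an [energy_landscape()].
#' @param th a [thermal_params()].
#' @param x displacement grid, nm.
#' @param z,y quadrature grids, nm.
#' @return data.frame with columns \code{x_nm}, \code{f_th_per_s},
#'   \code{g_th_per_s}.
#' @export
effective_rates <- function(kplus, kminus, E, th, x,
                            z = seq(-25, 25, length.out = 201L),
                            y = seq(-15, 25, length.out = 201L)) {
  stopifnot(is.function(kplus), is.function(kminus))
  p0 <- equilibrium_density_detached(E, th, z, y)
  f_th <- vapply(x, function(xx) {
    kz <- outer(z, y, function(zz, yy) kplus(zz, yy, xx))
    trapz2(z, y, kz * p0$p)
  }, numeric(1))
  g_th <- vapply(x, function(xx) {
    p1 <- equilibrium_density_attached(E, th, xx, y)
    trapz(y, kminus(y, xx) * p1$p)
  }, numeric(1))
  if (any(f_th < -1e-12) || any(g_th < -1e-12))
    stop("negative effective rate; check the microscopic rate functions")
  data.frame(x_nm = x, f_th_per_s = pmax(f_th, 0), g_th_per_s = pmax(g_th, 0))
}

# 2-D trapezoid rule on a tensor grid
trapz2 <- function(x, y, f) {
  wx <- diff(x); wx <- c(wx[1], wx[-1] + wx[-length(wx)], wx[length(wx)]) / 2
  wy <- diff(y); wy <- c(wy[1], wy[-1] + wy[-length(wy)], wy[length(wy)]) / 2
  as.numeric(wx %*% f %*% wy)
}
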