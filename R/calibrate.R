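#' Calibrate a crossbridge model from macroscopic measurements
#'
#' Closed-form inverse problem: given the five observables of
#' [measured_quantities()], determine the generalized two-state model
#' parameters exactly. In the linear-growth case
#' (\eqn{q(v) = \alpha|v|}):
#' \deqn{r_0 = \tilde k_2 v^0, \quad
#'       \alpha = \frac{\tilde k_2}{2}\left(1 - \frac{v^0}{v^{max}}\right),
#'       \quad \mu_f^0 = \frac{\mu^0_{iso} r_0}{P}, \quad
#'       \mu_f^1 = \frac{\mu_f^0}{\tilde k_2 - \alpha}, \quad
#'       a_{XB} = \frac{T_a^{iso} r_0}{\mu_f^1 P}.}
#' In the sublinear-growth case (\eqn{q = \alpha\sqrt{|v|}} in
#' simulation, with \eqn{\alpha} acting as the small-velocity linear
#' coefficient in the force-velocity closed forms):
#' \deqn{r_0 = \frac{2\tilde k_2 v^{max}}{1 + v^{max}/v^0}, \quad
#'       \alpha = \frac{v^{max} - v^0}{v^{max} + v^0}\tilde k_2, \quad
#'       \mu_f^1 = \mu_f^0 / \tilde k_2,}
#' with \eqn{\mu_f^0} and \eqn{a_{XB}} as above. A superlinear-growth
#' model (\eqn{q = \alpha(|v| + v^2)}) reuses the linear relations; no
#' fitting routine is bundled for it.
#'
#' The calibration is an exact algebraic inverse of
#' [characteristic_quantities()]: the forward map applied to the result
#' reproduces the inputs to machine precision.
#'
#' @param measurements an [measured_quantities()] object.
#' @param growth growth class of the destruction term.
#' @param P permissivity associated with the conditions under which
#'   \code{T_iso} and \code{mu0_iso} were measured. \code{P} enters only
#'   \eqn{\mu_f^0}, \eqn{\mu_f^1} and \eqn{a_{XB}}; all normalized
#'   predictions are P-invariant.
#' @param SL0,D_M filament geometry, nm.
#' @return A calibrated [xb_model()] (class \code{"xb_model"}) whose
#'   \code{calibration} field records the inputs.
#' @examples
#' meas <- measured_quantities(T_iso_kPa = 120, mu0_iso = 0.22,
#'                             v_max = 8, v0 = 2, k2 = 65)
#' fit <- xb_calibrate(meas, growth = "linear")
#' coef(fit)
#' summary(fit)
#' @export
xb_calibrate <- function(measurements,
                         growth = c("linear", "sublinear", "superlinear"),
                         P = 1, SL0 = 2200, D_M = 43) {
  stopifnot(inherits(measurements, "xb_measurements"), P > 0, P <= 1)
  growth <- match.arg(growth)
  ms <- measurements
  if (is.na(ms$v_max)) stop("calibration requires a finite v_max")
  if (ms$v0 > ms$v_max)
    stop("v0 > v_max: alpha would be negative; measurements are ",
         "inconsistent with a convex force-velocity curve")
  if (growth %in% c("linear", "superlinear")) {
    r0 <- ms$k2 * ms$v0
    alpha <- ms$k2 / 2 * (1 - ms$v0 / ms$v_max)
    mu_f0 <- ms$mu0_iso * r0 / P
    mu_f1 <- mu_f0 / (ms$k2 - alpha)
  } else {
    r0 <- 2 * ms$k2 * ms$v_max / (1 + ms$v_max / ms$v0)
    alpha <- (ms$v_max - ms$v0) / (ms$v_max + ms$v0) * ms$k2
    mu_f0 <- ms$mu0_iso * r0 / P
    mu_f1 <- mu_f0 / ms$k2
  }
  a_XB <- ms$T_iso_kPa * 1e3 * r0 / (mu_f1 * P)
  m <- xb_model(mu_f0 = mu_f0, mu_f1 = mu_f1, r0 = r0, alpha = alpha,
                growth = growth, a_XB = a_XB, P = P, SL0 = SL0, D_M = D_M)
  m$calibration <- list(measurements = ms, P = P)
  m
}

#' Forward map: model to measured quantities
#'
#' Convenience alias delegating to [characteristic_quantities()]; the
#' exact inverse of [xb_calibrate()].
#'
#' @param m an [xb_model()].
#' @return an [measured_quantities()] object.
#' @export
forward_measurements <- function(m) characteristic_quantities(m)

#' @export
print.xb_model <- function(x, ...) {
  cat("Generalized two-state crossbridge model (", x$growth,
      " destruction growth)\n", sep = "")
  cat(sprintf("  mu_f0 = %.6g 1/s   mu_f1 = %.6g 1/s   r0 = %.6g 1/s\n",
              x$mu_f0, x$mu_f1, x$r0))
  cat(sprintf("  alpha = %.6g        a_XB = %.6g MPa    P = %.3g\n",
              x$alpha, x$a_XB / 1e6, x$P))
  if (!is.null(x$calibration))
    cat("  (calibrated from macroscopic measurements)\n")
  invisible(x)
}

#' @export
coef.xb_model <- function(object, ...) {
  c(mu_f0_per_s = object$mu_f0, mu_f1_per_s = object$mu_f1,
    r0_per_s = object$r0, alpha = object$alpha,
    a_XB_MPa = object$a_XB / 1e6)
}

#' @export
summary.xb_model <- function(object, ...) {
  cq <- suppressWarnings(characteristic_quantities(object))
  structure(list(model = object, characteristic = cq),
            class = "summary.xb_model")
}

#' @export
print.summary.xb_model <- function(x, ...) {
  print(x$model)
  cat("\nImplied macroscopic quantities:\n")
  print(x$characteristic)
  if (!is.null(x$model$calibration)) {
    res <- residuals(x$model)
    cat("\nMax |relative calibration residual|:",
        format(max(abs(res)), digits = 3), "\n")
  }
  invisible(x)
}

#' Predict from a crossbridge model
#'
#' @param object an [xb_model()].
#' @param v normalized velocity grid, 1/s; defaults to 60 points from 0
#'   to the zero crossing of the simulated curve (or \code{1.2 * v0 *
#'   10} when no crossing exists).
#' @param type \code{"force_velocity"} returns the steady curve (data
#'   frame \code{v_per_s}, \code{T_norm}, \code{T_kPa});
#'   \code{"moments"} the steady moments; \code{"measurements"} the
#'   forward characteristic quantities.
#' @param ... unused.
#' @return see \code{type}.
#' @export
predict.xb_model <- function(object, v = NULL,
                             type = c("force_velocity", "moments",
                                      "measurements"), ...) {
  type <- match.arg(type)
  if (type == "measurements") return(characteristic_quantities(object))
  if (is.null(v)) {
    vz <- simulated_vmax(object)
    v <- seq(0, 1.05 * vz, length.out = 60L)
  }
  s <- steady_moments(object, v)
  if (type == "moments")
    return(data.frame(v_per_s = v, mu0 = s$mu0, mu1 = s$mu1))
  T_iso <- steady_moments(object, 0)$T_Pa
  data.frame(v_per_s = v, T_norm = s$T_Pa / T_iso, T_kPa = s$T_Pa / 1e3)
}

# zero crossing of the simulated steady tension (uses the model's own q)
simulated_vmax <- function(m) {
  f <- function(v) steady_moments(m, v)$mu1
  hi <- m$r0 / max(m$mu_f0 / m$mu_f1 / 2, 1e-8)
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) > 0) return(NA_real_)
  stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

#' Calibration residuals
#'
#' Relative discrepancies between the measurements a model was
#' calibrated from and the quantities implied by its parameters. Zero
#' to machine precision for models produced by [xb_calibrate()] (the
#' calibration is an exact inverse); useful as a self-check after
#' manual parameter edits.
#'
#' @param object an [xb_model()] with a calibration record.
#' @param ... unused.
#' @return named numeric vector of relative residuals.
#' @export
residuals.xb_model <- function(object, ...) {
  if (is.null(object$calibration))
    stop("model was not produced by xb_calibrate(); no residuals defined")
  ms <- object$calibration$measurements
  cq <- suppressWarnings(characteristic_quantities(object))
  obs <- c(T_iso_kPa = ms$T_iso_kPa, mu0_iso = ms$mu0_iso,
           v_max = ms$v_max, v0 = ms$v0, k2 = ms$k2)
  pred <- c(cq$T_iso_kPa, cq$mu0_iso, cq$v_max, cq$v0, cq$k2)
  (pred - obs) / obs
}

#' Simulate noisy virtual measurements from a model
#'
#' Wrapper around [generate_noisy_measurements()] following the base R
#' \code{simulate} contract: returns a list of \code{nsim} synthetic
#' datasets, reproducible for a given \code{seed}.
#'
#' @param object an [xb_model()].
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param sigma noise standard deviation on normalized tension.
#' @param ... passed to [generate_noisy_measurements()].
#' @return list of \code{"xb_dataset"} objects (a single dataset if
#'   \code{nsim = 1}).
#' @export
simulate.xb_model <- function(object, nsim = 1, seed = 1, sigma = 0.02, ...) {
  out <- lapply(seq_len(nsim), function(i)
    generate_noisy_measurements(object, sigma = sigma,
                                seed = seed + i - 1L, ...))
  if (nsim == 1L) out[[1L]] else out
}

#' Plot a crossbridge model
#'
#' Two base-graphics panels: the steady normalized force-velocity curve
#' and the end-of-step tension against step size (fast protocol and the
#' instantaneous-step asymptote).
#'
#' @param x an [xb_model()].
#' @param delta_t step duration for the quick-release panel, s.
#' @param ... unused.
#' @export
plot.xb_model <- function(x, delta_t = 200e-6, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  fv <- predict(x, type = "force_velocity")
  plot(fv$v_per_s, fv$T_norm, type = "l", xlab = "v [1/s]",
       ylab = expression(T[a] / T[a]^iso), main = "Force-velocity")
  graphics::abline(h = 0, lty = 3)
  dL <- seq(0, 0.06, length.out = 25L)
  T_iso <- steady_moments(x, 0)$T_Pa
  Tend <- end_of_step_tension(x, dL, delta_t = delta_t) / T_iso
  Tasym <- asymptotic_step_tension(x, dL) / T_iso
  plot(dL, Tend, type = "l", xlab = expression(Delta * L),
       ylab = expression(T[a](delta) / T[a]^iso), main = "Quick release")
  graphics::lines(dL, Tasym, lty = 2)
  graphics::legend("topright", lty = c(1, 2), bty = "n",
                   legend = c(sprintf("dt = %g s", delta_t),
                              "instantaneous-step asymptote"))
  invisible(x)
}
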