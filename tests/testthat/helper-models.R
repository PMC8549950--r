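# Shared fixtures, all built in code.

# Intact-rat cardiac measurements; k2 defaults to the value consistent
# with the published calibrated rate constants (r0 = 130 = k2 * v0).
rat_measurements <- function(k2 = 65) {
  measured_quantities(T_iso_kPa = 120, mu0_iso = 0.22,
                      v_max = 8, v0 = 2, k2 = k2)
}

linear_model <- function(P = 1) xb_calibrate(rat_measurements(), "linear", P = P)
sublinear_model <- function(P = 1) xb_calibrate(rat_measurements(), "sublinear", P = P)

superlinear_model <- function() {
  # superlinear destruction reuses the linear-growth calibration relations
  xb_calibrate(rat_measurements(), "superlinear")
}

# Classic skeletal-muscle two-state rate constants
classic_rates <- function() huxley_rate_params(f1 = 65, g1 = 15, g2 = 313.5, h = 10)

# random admissible measurement vectors for property tests
random_measurements <- function(n) {
  lapply(seq_len(n), function(i) {
    v0 <- stats::runif(1, 0.5, 4)
    v_max <- v0 * stats::runif(1, 1.2, 8)
    measured_quantities(
      T_iso_kPa = stats::runif(1, 30, 300),
      mu0_iso = stats::runif(1, 0.05, 0.6),
      v_max = v_max, v0 = v0,
      k2 = stats::runif(1, 10, 120))
  })
}
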