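test_that("Hill hyperbola utilities match their algebra", {
  p <- hill_params(a_over_Tiso = 0.22, b = 0.27, T_iso_kPa = 120)
  expect_equal(hill_tension(0, p), 120)
  expect_equal(hill_tension(hill_vmax(p), p), 0, tolerance = 1e-12)
  # direct algebraic solution at an interior point
  v <- 0.1
  a <- 0.22 * 120
  expect_equal(hill_tension(v, p), (0.27 * 120 - a * v) / (0.27 + v))
  # vmax proportional to b; zero when the muscle cannot shorten
  expect_equal(hill_vmax(hill_params(0.22, 2 * 0.27)), 2 * hill_vmax(p))
  expect_equal(hill_vmax(hill_params(0.22, 0)), 0)
})

test_that("fiber velocity normalization uses explicit units", {
  # 1.03 cm/s on a 38 mm fiber
  b <- normalize_fiber_velocity(10.3, 38)
  expect_equal(b, 0.27, tolerance = 2e-2)
  expect_equal(normalize_fiber_velocity(5, 5), 1)
  expect_error(normalize_fiber_velocity(1, 0), "positive")
})

test_that("force-velocity sweep is normalized, convex, and P-invariant", {
  m <- linear_model()
  v <- seq(0, 8, length.out = 81)
  fv <- run_force_velocity(m, v)
  expect_equal(fv$T_norm[1], 1)
  expect_equal(fv$T_norm[81], 0, tolerance = 1e-12)
  # matches the closed form in the linear case
  expect_equal(fv$T_norm, normalized_force_velocity(m, v), tolerance = 1e-12)
  # convex decreasing: nonnegative second differences
  expect_true(all(diff(fv$T_norm) < 0))
  expect_true(all(diff(diff(fv$T_norm)) >= -1e-12))
  # permissivity leaves the normalized curve unchanged
  fvP <- run_force_velocity(linear_model(P = 0.5), v)
  expect_equal(fvP$T_norm, fv$T_norm, tolerance = 1e-12)
})

test_that("quick-release traces start isometric, drop, and recover", {
  m <- sublinear_model()
  T_iso <- steady_moments(m, 0)$T_Pa
  # no step: flat trace
  tr0 <- run_length_step(m, step_protocol(0, 200e-6), t_end = 0.05)
  expect_equal(tr0$T_Pa, rep(T_iso, nrow(tr0)), tolerance = 1e-12)
  # end-of-step value agrees with the exact expression
  st <- step_protocol(0.03, 200e-6)
  tr <- run_length_step(m, st, t_end = 0.08)
  i_end <- max(which(tr$t_s <= st$delta_t))
  expect_equal(tr$T_Pa[i_end], end_of_step_tension(m, st), tolerance = 1e-6)
  expect_equal(tr$T_norm[1], 1)
  # recovery toward the isometric level at rate r0
  expect_lt(abs(tr$T_Pa[nrow(tr)] - T_iso) / T_iso, 1e-3)
  post <- tr[tr$t_s > st$delta_t, ]
  expect_true(all(diff(post$T_Pa) > 0))
  lhs <- log(abs(T_iso - post$T_Pa[2]) / abs(T_iso - post$T_Pa[10]))
  expect_equal(lhs, m$r0 * (post$t_s[10] - post$t_s[2]), tolerance = 1e-6)
})

test_that("small-step drop slope of the fast protocol approaches k2", {
  m <- sublinear_model()
  T_iso <- steady_moments(m, 0)$T_Pa
  dL <- 1e-3
  slope <- (T_iso - end_of_step_tension(m, dL, delta_t = 1e-10)) / T_iso / dL
  expect_equal(slope, characteristic_quantities(m)$k2, tolerance = 1e-3)
})

test_that("slower steps lie above faster steps, which lie above the asymptote", {
  # heartbeat-speed step: constant velocity 0.5 1/s, duration dL / 0.5
  slow_fast_asym <- function(m, dL) {
    list(asym = asymptotic_step_tension(m, dL),
         fast = end_of_step_tension(m, dL, delta_t = 200e-6),
         slow = vapply(dL, function(d)
           end_of_step_tension(m, d, delta_t = d / 0.5), numeric(1)))
  }
  # linear destruction: ordering holds for every positive step size
  dL <- seq(0.002, 0.06, length.out = 20)
  ml <- linear_model()
  Tl <- slow_fast_asym(ml, dL)
  expect_true(all(Tl$slow >= Tl$fast - 1e-9))
  expect_true(all(Tl$fast >= Tl$asym - 1e-9))
  expect_gt(Tl$slow[20] - Tl$asym[20], 0.05 * steady_moments(ml, 0)$T_Pa)
  # sublinear sqrt destruction: during a finite step the destruction loss
  # scales as alpha*sqrt(dL*delta) while recovery gains only r0*delta, so
  # for very small steps a slower ramp loses slightly more tension and the
  # strict ordering inverts; in the saturation region it holds as in the
  # linear case
  ms <- sublinear_model()
  dLs <- dL[dL >= 0.02]
  Tsub <- slow_fast_asym(ms, dLs)
  expect_true(all(Tsub$slow >= Tsub$fast - 1e-9))
  expect_true(all(Tsub$fast >= Tsub$asym - 1e-9))
  expect_gt(Tsub$slow[length(dLs)] - Tsub$asym[length(dLs)],
            0.05 * steady_moments(ms, 0)$T_Pa)
})

test_that("superlinear destruction drives the end-step tension to zero", {
  m <- superlinear_model()
  dL <- 0.03
  Ts <- vapply(c(1e-3, 1e-5, 1e-7), function(d)
    end_of_step_tension(m, dL, delta_t = d), numeric(1))
  expect_true(all(diff(Ts) < 0))
  expect_lt(Ts[3] / steady_moments(m, 0)$T_Pa, 0.02)
})

test_that("synthetic datasets are reproducible and honest about their noise", {
  m <- linear_model()
  # zero noise: points lie exactly on the model curves
  d0 <- generate_noisy_measurements(m, sigma = 0, seed = 3)
  T_iso <- steady_moments(m, 0)$T_Pa
  expect_equal(d0$fv$T_kPa,
               steady_moments(m, d0$fv$v_per_s)$T_Pa / 1e3, tolerance = 1e-12)
  expect_equal(d0$steps$T_norm,
               end_of_step_tension(m, d0$steps$delta_L,
                                   delta_t = d0$steps$delta_t_s[1]) / T_iso,
               tolerance = 1e-12)
  # reproducibility and RNG hygiene
  set.seed(999); before <- rnorm(1)
  set.seed(999)
  d1 <- generate_noisy_measurements(m, sigma = 0.02, seed = 11)
  after <- rnorm(1)
  expect_identical(before, after)  # generator restores the RNG state
  d2 <- generate_noisy_measurements(m, sigma = 0.02, seed = 11)
  expect_identical(d1, d2)
  # realized noise close to nominal sigma
  d3 <- generate_noisy_measurements(m, sigma = 0.02, n_fv = 400, seed = 5)
  resid <- d3$fv$T_kPa * 1e3 / T_iso -
    steady_moments(m, d3$fv$v_per_s)$T_Pa / T_iso
  expect_equal(stats::sd(resid), 0.02, tolerance = 0.15)
  # simulate() method wraps the generator
  expect_identical(simulate(m, seed = 11, sigma = 0.02), d1)
})

test_that("noiseless recovery returns the generating measurements exactly", {
  m <- linear_model()
  d <- generate_noisy_measurements(m, sigma = 0, seed = 2)
  rec <- recover_measurements(d)
  expect_equal(rec$T_iso_kPa, 120, tolerance = 1e-6)
  expect_equal(rec$mu0_iso, 0.22, tolerance = 1e-6)
  expect_equal(rec$v_max, 8, tolerance = 1e-6)
  expect_equal(rec$v0, 2, tolerance = 1e-6)
  expect_equal(rec$k2, 65, tolerance = 1e-6)
})

test_that("measure-calibrate-simulate-recover closes the loop on the rat data", {
  fit <- xb_calibrate(rat_measurements(), "linear")
  d <- generate_noisy_measurements(fit, sigma = 0, seed = 8)
  rec <- recover_measurements(d)
  ms <- rat_measurements()
  for (f in c("T_iso_kPa", "mu0_iso", "v_max", "v0", "k2"))
    expect_equal(rec[[f]], ms[[f]], tolerance = 1e-6)
})

test_that("noisy recovery is close to unbiased over replicates", {
  m <- linear_model()
  n_rep <- 200
  est <- t(vapply(seq_len(n_rep), function(i) {
    r <- recover_measurements(
      generate_noisy_measurements(m, sigma = 0.02, seed = 1000 + i))
    c(r$T_iso_kPa, r$v_max, r$v0, r$k2)
  }, numeric(4)))
  truth <- c(120, 8, 2, 65)
  med <- apply(est, 2, stats::median)
  # median relative error of v_max under 5%
  expect_lt(stats::median(abs(est[, 2] - 8) / 8), 0.05)
  # medians of all recovered quantities within a few percent of truth
  expect_true(all(abs(med - truth) / truth < 0.05))
})
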