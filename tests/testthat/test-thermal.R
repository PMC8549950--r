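th_room <- thermal_params(4.1)

# quadratic landscape whose Boltzmann density is exactly Gaussian
gaussian_landscape <- function(k0 = 5, ke = 2) {
  energy_landscape(u0 = function(y) k0 * y^2 / 2,
                   u1 = function(y) k0 * y^2 / 2,
                   u_e = function(s) ke * s^2 / 2)
}

test_that("detached equilibrium density matches the Gaussian closed form", {
  k0 <- 5; ke <- 2
  E <- gaussian_landscape(k0, ke)
  z <- seq(-15, 15, length.out = 301)
  y <- seq(-10, 10, length.out = 301)
  p0 <- equilibrium_density_detached(E, th_room, z, y)
  expect_true(all(p0$p >= 0))
  # normalization
  num <- function(f) {
    wts <- outer(z, y, f) * p0$p
    xbridge:::trapz2(z, y, wts)
  }
  expect_equal(num(function(zz, yy) 1 + 0 * zz), 1, tolerance = 1e-10)
  # second moments equal kBT * H^{-1} for precision H
  H <- matrix(c(ke, ke, ke, k0 + ke), 2, 2)
  S <- th_room$kBT * solve(H)
  expect_equal(num(function(zz, yy) zz^2), S[1, 1], tolerance = 1e-8)
  expect_equal(num(function(zz, yy) yy^2), S[2, 2], tolerance = 1e-8)
  expect_equal(num(function(zz, yy) zz * yy), S[1, 2], tolerance = 1e-8)
})

test_that("densities are gauge invariant and normalized under refinement", {
  E <- gaussian_landscape()
  E_shift <- energy_landscape(u0 = function(y) E$u0(y) + 12.3,
                              u1 = E$u1, u_e = E$u_e)
  z <- seq(-15, 15, length.out = 201)
  y <- seq(-10, 10, length.out = 201)
  p_a <- equilibrium_density_detached(E, th_room, z, y)
  p_b <- equilibrium_density_detached(E_shift, th_room, z, y)
  expect_equal(p_a$p, p_b$p, tolerance = 1e-12)
  for (n in c(101, 201, 401)) {
    zz <- seq(-15, 15, length.out = n)
    yy <- seq(-10, 10, length.out = n)
    pp <- equilibrium_density_detached(E, th_room, zz, yy)
    expect_equal(xbridge:::trapz2(zz, yy, pp$p), 1, tolerance = 1e-8)
  }
})

test_that("attached equilibrium density is Gaussian for a single-well energy", {
  k1 <- 3; ke <- 2
  E <- energy_landscape(u0 = function(y) k1 * y^2 / 2,
                        u1 = function(y) k1 * y^2 / 2,
                        u_e = function(s) ke * s^2 / 2)
  x <- -4
  y <- seq(-12, 12, length.out = 2001)
  p1 <- equilibrium_density_attached(E, th_room, x, y)
  expect_equal(xbridge:::trapz(y, p1$p), 1, tolerance = 1e-10)
  # w1 = k1 y^2/2 + ke (x+y)^2/2: Gaussian with mean -ke x/(k1+ke)
  mean_ref <- -ke * x / (k1 + ke)
  var_ref <- th_room$kBT / (k1 + ke)
  expect_equal(xbridge:::trapz(y, y * p1$p), mean_ref, tolerance = 1e-8)
  expect_equal(xbridge:::trapz(y, (y - mean_ref)^2 * p1$p), var_ref,
               tolerance = 1e-8)
})

test_that("a deep post-power-stroke well captures nearly all attached mass", {
  tl <- toy_landscape()
  cold <- thermal_params(1)
  y <- seq(-8, 18, length.out = 1601)
  p1 <- equilibrium_density_attached(tl, cold, x = -6, y = y)
  mass_post <- xbridge:::trapz(y[y > 4], p1$p[y > 4])
  expect_gt(mass_post, 0.99)
})

test_that("constant microscopic rates pass through the reduction unchanged", {
  E <- gaussian_landscape()
  z <- seq(-15, 15, length.out = 201)
  y <- seq(-10, 10, length.out = 201)
  er <- effective_rates(function(z, y, x) 0 * z + 7,
                        function(y, x) 0 * y + 3,
                        E, th_room, x = c(-2, 0, 2), z = z, y = y)
  expect_equal(er$f_th_per_s, rep(7, 3), tolerance = 1e-10)
  expect_equal(er$g_th_per_s, rep(3, 3), tolerance = 1e-10)
})

test_that("freezing the power-stroke variable recovers the two-state rates", {
  # very stiff internal energy pins y ~ 0 in both states
  stiff <- 1e4
  E <- energy_landscape(u0 = function(y) stiff * y^2 / 2,
                        u1 = function(y) stiff * y^2 / 2,
                        u_e = function(s) 2 * s^2 / 2)
  z <- seq(-15, 15, length.out = 301)
  y <- seq(-0.6, 0.6, length.out = 601)
  f_hat <- function(x) 10 + x^2          # attachment independent of z, y
  g_hat <- function(x) 100 + 5 * x
  xg <- c(-3, 0, 2)
  er <- effective_rates(function(z, y, x) 0 * z + f_hat(x),
                        function(y, x) g_hat(x) + 50 * y,
                        E, th_room, x = xg, z = z, y = y)
  expect_equal(er$f_th_per_s, f_hat(xg), tolerance = 1e-10)
  # g averages k_-(y, x) against a density concentrated at y = 0
  expect_equal(er$g_th_per_s, g_hat(xg), tolerance = 1e-3)
})

test_that("effective-rate quadrature converges under grid refinement", {
  # classical O(h^2) of the trapezoid rule, on an integrand with mass at
  # the window boundary (for decayed Boltzmann tails the Euler-Maclaurin
  # boundary terms vanish and convergence is much faster than h^2)
  f_exact <- (exp(1) - exp(-1))^2 / 4  # int of e^z e^y /4 on [-1,1]^2
  e_h <- vapply(c(21, 41, 81), function(n) {
    z <- seq(-1, 1, length.out = n)
    abs(xbridge:::trapz2(z, z, outer(z, z, function(a, b)
      exp(a + b) / 4)) - f_exact)
  }, numeric(1))
  expect_gt(e_h[1] / e_h[2], 3.5)
  expect_lt(e_h[1] / e_h[2], 4.5)
  expect_gt(e_h[2] / e_h[3], 3.5)
  expect_lt(e_h[2] / e_h[3], 4.5)

  # effective rates on the toy landscape: refinement error collapses
  tl <- toy_landscape()
  kplus <- function(z, y, x) 5 / (1 + exp(-(y - 3)))  # smooth, bounded
  kminus <- function(y, x) 2 + 0 * y
  f_at <- function(n) {
    z <- seq(-25, 25, length.out = n)
    y <- seq(-15, 25, length.out = n)
    effective_rates(kplus, kminus, tl, th_room, x = 0,
                    z = z, y = y)$f_th_per_s
  }
  ref <- f_at(1601)
  e1 <- abs(f_at(51) - ref)
  e2 <- abs(f_at(101) - ref)
  e3 <- abs(f_at(201) - ref)
  expect_gt(e1, e2)
  expect_gt(e2, e3)
  expect_lt(e3 / abs(ref), 1e-10)
})

test_that("quadrature rates agree with a Monte Carlo estimate on the toy landscape", {
  tl <- toy_landscape()
  z <- seq(-25, 25, length.out = 401)
  y <- seq(-15, 25, length.out = 401)
  kplus <- function(z, y, x) 4 / (1 + exp(-(z + y - 2)))
  kminus <- function(y, x) 1 + 2 * exp(-(y - 8)^2 / 4)
  x0 <- -3
  er <- effective_rates(kplus, kminus, tl, th_room, x = x0, z = z, y = y)

  # rejection sampling from the detached Boltzmann density
  set.seed(2024)
  p0 <- equilibrium_density_detached(tl, th_room, z, y)
  pmax0 <- max(p0$p)
  n_try <- 4e6
  zc <- stats::runif(n_try, min(z), max(z))
  yc <- stats::runif(n_try, min(y), max(y))
  w <- exp(-(tl$u0(yc) + tl$u_e(zc + yc) -
               min(p0$w)) / th_room$kBT)
  acc <- stats::runif(n_try) < w / max(w)
  zs <- zc[acc]; ys <- yc[acc]
  ksamp <- kplus(zs, ys, x0)
  mc_f <- mean(ksamp); se_f <- stats::sd(ksamp) / sqrt(length(ksamp))
  expect_lt(abs(er$f_th_per_s - mc_f), 3 * se_f + 1e-6)

  # attached density is one-dimensional: sample by inverse CDF on the grid
  p1 <- equilibrium_density_attached(tl, th_room, x = x0, y = y)
  cdf <- cumsum(p1$p); cdf <- cdf / max(cdf)
  ys1 <- y[findInterval(stats::runif(5e5), cdf) + 1L]
  ks1 <- kminus(ys1, x0)
  mc_g <- mean(ks1); se_g <- stats::sd(ks1) / sqrt(length(ks1))
  expect_lt(abs(er$g_th_per_s - mc_g), 3 * se_g + 2e-3)
})
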