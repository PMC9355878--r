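test_that("strain follows 1 - h_eq/h0 and rejects bad geometry", {
  expect_equal(strain(2, 1.5), 0.25)
  expect_equal(strain(1, 0.75), 0.25)   # 75% of original height = 25% strain
  expect_equal(strain(3, 3), 0)
  expect_error(strain(1, 1.1), "h_eq exceeds h0")
  expect_error(strain(-1, 0.5), "positive")
})

test_that("effective resistance matches hand evaluation and scales with curvature", {
  geom <- plate_geometry(h0 = 2, h_eq = 1.5, L = 2.4, R1 = 1, R2 = 1, R3 = 0.5)
  expect_equal(equilibrium_stress(78.53982, 0.5), 100, tolerance = 1e-6)
  expect_equal(effective_resistance(78.53982, geom), 0.05, tolerance = 1e-6)
  expect_equal(effective_resistance(0, geom), 0)
  geom2 <- plate_geometry(h0 = 2, h_eq = 1.5, L = 2.4, R1 = 2, R2 = 2, R3 = 0.5)
  expect_equal(effective_resistance(10, geom2),
               2 * effective_resistance(10, geom))
  expect_error(plate_geometry(2, 1.5, 2.4, -1, 1, 0.5), "positive")
})

test_that("sigma via SI equals sigma via bench units to machine precision", {
  geom <- plate_geometry(h0 = 1.8, h_eq = 1.35, L = 2, R1 = 0.9, R2 = 1.1,
                         R3 = 0.45)
  F_eq <- 63.7
  bench <- (F_eq / (pi * geom$R3^2)) / (1 / geom$R1 + 1 / geom$R2) * 1e-3
  expect_equal(effective_resistance(F_eq, geom), bench, tolerance = 1e-14)
})

test_that("Young's modulus divides stress by strain and diverges as strain vanishes", {
  expect_equal(youngs_modulus(78.53982, 0.5, 0.25), 400, tolerance = 1e-6)
  expect_equal(youngs_modulus(50, 0.5, 1), equilibrium_stress(50, 0.5))
  expect_equal(youngs_modulus(0, 0.5, 0.2), 0)
  expect_error(youngs_modulus(50, 0.5, 0), "invalid strain")
  eps_seq <- 10^seq(-1, -6, by = -1)
  E_seq <- vapply(eps_seq, function(e) youngs_modulus(10, 0.5, e), numeric(1))
  expect_true(all(diff(E_seq) > 0))
})

test_that("side-view volume formula reproduces the spherical limit and scaling", {
  r <- 0.7
  expect_equal(ln_volume_from_sideview(r, 2 * r), 4 / 3 * pi * r^3)
  expect_equal(ln_volume_from_sideview(1, 2), 4.18879, tolerance = 1e-5)
  expect_equal(ln_volume_from_sideview(1, 4), 4 * ln_volume_from_sideview(1, 2))
})

test_that("relaxation fit handles degenerate and noiseless traces", {
  tr <- force_trace(0:19, rep(5, 20))
  fit <- fit_relaxation(tr)
  expect_equal(fit$F_eq, 5)
  expect_equal(fit$A1 + fit$A2, 0)
  expect_equal(fit$rss, 0)

  g <- gen_relaxation_trace(noise_sd = 0, seed = 1)
  fit <- fit_relaxation(g$trace)
  expect_lt(abs(fit$F_eq - 40) / 40, 1e-5)
  expect_lt(abs(fit$tau1 - 5) / 5, 1e-4)
  expect_lt(abs(fit$tau2 - 300) / 300, 1e-4)
  expect_lt(fit$tau1, fit$tau2)          # canonical ordering
})

test_that("relaxation fit recovers parameters from a noisy trace within 5%", {
  g <- gen_relaxation_trace(noise_sd = 0.4, seed = 11)
  fit <- fit_relaxation(g$trace)
  expect_lt(abs(fit$F_eq - g$truth$F_eq) / g$truth$F_eq, 0.05)
  expect_lt(abs(fit$A1 - g$truth$A1) / g$truth$A1, 0.05)
  expect_lt(abs(fit$tau2 - g$truth$tau2) / g$truth$tau2, 0.05)
})

test_that("single-exponential traces yield one vanishing amplitude", {
  t <- seq(0, 900)
  f <- 40 + 30 * exp(-t / 5)
  fit <- fit_relaxation(force_trace(t, f))
  small <- min(abs(fit$A1), abs(fit$A2))
  big_tau <- if (abs(fit$A1) > abs(fit$A2)) fit$tau1 else fit$tau2
  big_amp <- max(abs(fit$A1), abs(fit$A2))
  expect_lt(small / 30, 0.02)
  expect_lt(abs(big_amp - 30) / 30, 0.02)
  expect_lt(abs(big_tau - 5) / 5, 0.05)
})

test_that("trace validation rejects malformed inputs and short tails flag viscosity", {
  expect_error(force_trace(c(1, 2, 2, 3:9, 10), rep(1, 11)), "increasing")
  expect_error(force_trace(1:9, rep(1, 9)), "length")
  expect_error(force_trace(1:10, c(-1, rep(1, 9))), "non-negative")
  # recording much shorter than the slow timescale: flagged, not dropped
  g <- gen_relaxation_trace(tau2 = 300, duration = 400, noise_sd = 0, seed = 2)
  fit <- fit_relaxation(g$trace)
  expect_true(fit$viscosity_undetermined)
})

test_that("spring/dashpot mapping obeys mu = k tau and round-trips the generator", {
  geom <- plate_geometry(h0 = 2, h_eq = 1.5, L = 2.4, R1 = 1, R2 = 1, R3 = 0.5)
  # A2 chosen so that k2 = 10 Pa at eps = 0.25: A2 = 10 * 0.25 * pi * 0.25
  A2 <- 10 * 0.25 * pi * 0.5^2
  fit <- structure(list(F_eq = 40, A1 = 0, A2 = A2, tau1 = 5, tau2 = 300,
                        rss = 0), class = "kelvin_fit")
  v <- viscosities(fit, geom, 0.25)
  expect_equal(v$k2, 10, tolerance = 1e-12)
  expect_equal(v$mu2, 3000, tolerance = 1e-12)
  expect_equal(v$mu1, 0)   # absent fast branch here

  g <- gen_relaxation_trace(noise_sd = 0.4, seed = 21)
  fr <- fit_relaxation(g$trace)
  vr <- viscosities(fr, g$geometry, g$truth$eps)
  expect_lt(abs(vr$mu1 - g$truth$mu1) / g$truth$mu1, 0.05)
  expect_lt(abs(vr$mu2 - g$truth$mu2) / g$truth$mu2, 0.05)
})

test_that("aspiration modulus implements Laplace's law", {
  expect_equal(aspiration_modulus(aspiration_measurement(500, 10, 10)), 500)
  m <- aspiration_measurement(750, 15, 7.5)
  expect_equal(aspiration_modulus(m), 3000)
  m2 <- aspiration_measurement(750, 15, 15)
  expect_equal(aspiration_modulus(m2), aspiration_modulus(m) / 4)
  expect_error(aspiration_modulus(aspiration_measurement(750, 15, 0)),
               "no aspiration")
})

test_that("passive tension is the modulus-thickness product in SI", {
  expect_equal(passive_tension(1000, 10), 0.01)
  expect_equal(passive_tension(1000, 0), 0)
  expect_equal(passive_tension(2 * 1000, 14 * 10), 28 * passive_tension(1000, 10))
})

test_that("analyze_relaxation assembles all derived quantities consistently", {
  g <- gen_relaxation_trace(noise_sd = 0, seed = 3)
  tm <- analyze_relaxation(g$trace, g$geometry)
  expect_equal(tm$strain, 0.25)
  expect_equal(tm$E, tm$stress / tm$strain)
  expect_lt(abs(tm$sigma - g$truth$sigma) / g$truth$sigma, 1e-4)
  expect_lt(abs(tm$volume - ln_volume_from_sideview(1, 2)), 1e-12)
  expect_output(print(tm), "effective resistance")
})
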