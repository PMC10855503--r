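test_that("dry-basis moisture follows its definition and rejects bad input", {
  expect_equal(dry_basis_moisture(23.6, 23.6), 0)
  expect_equal(dry_basis_moisture(2 * 23.6, 23.6), 1)
  # a fresh sample at 84.28% wet basis carries 5.362 g water per g dry matter
  expect_equal(wet_to_dry_basis(0.8428), 0.8428 / (1 - 0.8428))
  expect_equal(wet_to_dry_basis(0.8428), 5.362, tolerance = 2e-4)
  expect_error(dry_basis_moisture(10, 0), class = "dryopt_invalid_input")
  expect_error(dry_basis_moisture(5, 10), class = "dryopt_invalid_input")
})

test_that("moisture ratio normalizes to 1 at time zero and round-trips the generator", {
  cv <- drying_curve(c(0, 15, 30), c(150, 140, 130), dry_mass = 23.6)
  ms <- moisture_ratio_series(cv)
  expect_identical(ms$mr[1], 1)

  flat <- drying_curve(c(0, 15, 30), rep(100, 3), dry_mass = 40)
  expect_true(all(moisture_ratio_series(flat)$mr == 1))

  # construct masses from MR(t) = exp(-0.02 t) and recover it exactly
  t <- seq(0, 300, by = 15)
  m0 <- 5.362; dry <- 25
  masses <- dry * (1 + m0 * exp(-0.02 * t))
  ms <- moisture_ratio_series(drying_curve(t, masses, dry))
  expect_equal(ms$mr, exp(-0.02 * t), tolerance = 1e-12)

  bone_dry <- drying_curve(c(0, 15, 30), rep(25, 3), dry_mass = 25)
  expect_error(moisture_ratio_series(bone_dry), class = "dryopt_invalid_input")
})

test_that("drying rate is the per-interval moisture loss", {
  t <- seq(0, 150, by = 15)
  const <- data.frame(time = t, moisture = rep(3, length(t)))
  expect_true(all(drying_rate_series(const)$rate == 0))

  lin <- data.frame(time = t, moisture = 5 - 0.01 * t)
  expect_equal(drying_rate_series(lin)$rate, rep(0.01, length(t) - 1))

  two <- data.frame(time = c(0, 15), moisture = c(5.0, 4.7))
  expect_equal(drying_rate_series(two)$rate, 0.02)
  expect_equal(drying_rate_series(two)$mid_moisture, 4.85)

  dup <- data.frame(time = c(0, 0, 15), moisture = c(5, 5, 4))
  expect_error(drying_rate_series(dup), class = "dryopt_invalid_input")
})

test_that("thin-layer fit recovers exact log-linear series and matches an OLS oracle", {
  t <- seq(0, 10, by = 0.5)
  # series built exactly from ln MR = -0.3275 t + 0.175
  s <- data.frame(time = t, mr = exp(-0.3275 * t + 0.175))
  fit <- fit_thin_layer(s)
  expect_equal(fit$slope, 0.3275, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.175, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # pure exponential: zero intercept, unit R^2
  s2 <- data.frame(time = t, mr = exp(-0.11 * t))
  fit2 <- fit_thin_layer(s2)
  expect_equal(fit2$slope, 0.11, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)

  # noisy series against the two-pass normal-equations oracle
  set.seed(11)
  noisy <- data.frame(time = t, mr = exp(-0.2 * t + rnorm(length(t), 0, 0.05)))
  fit3 <- fit_thin_layer(noisy)
  beta <- ols_oracle(cbind(1, t), log(noisy$mr))
  expect_equal(fit3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(-fit3$slope, beta[2], tolerance = 1e-10)

  bad <- data.frame(time = c(0, 1, 2), mr = c(1, 0.5, 0))
  expect_error(fit_thin_layer(bad), class = "dryopt_invalid_input")
})

test_that("effective diffusivity follows the slab slope formula and the tabulated calibration", {
  expect_equal(deff_from_slope(0, 0.006)$d_eff, 0)
  # unit identity: slope pi^2 per second, L = 1 m
  expect_equal(deff_from_slope(pi^2, 1, time_unit_scale = 1)$d_eff, 1)

  # tabulated calibration reproduces the published slope -> D_eff pairs
  d50 <- deff_from_slope(0.2375, calibration = deff_reference_calibration)
  d60 <- deff_from_slope(0.3275, calibration = deff_reference_calibration)
  expect_equal(d50$d_eff, 8.55e-9, tolerance = 5e-3)
  expect_equal(d60$d_eff, 1.18e-8, tolerance = 5e-3)

  # linearity: D_eff ratios equal slope ratios exactly
  expect_equal(d60$d_eff / d50$d_eff, 0.3275 / 0.2375, tolerance = 1e-12)
  # and the tabulated 60/50 pair agrees with that ratio to 3 significant digits
  expect_equal(signif(1.18e-8 / 8.55e-9, 3), signif(0.3275 / 0.2375, 3))

  expect_error(deff_from_slope(0.3, 0), class = "dryopt_invalid_input")
  expect_error(deff_from_slope(0.3, 0.006, time_unit_scale = -1),
               class = "dryopt_invalid_input")
})

test_that("drying curves validate their physical invariants", {
  expect_error(drying_curve(c(5, 15, 30), c(3, 2, 1), 1),
               class = "dryopt_invalid_input")       # t0 != 0
  expect_error(drying_curve(c(0, 15, 15), c(3, 2, 1), 1),
               class = "dryopt_invalid_input")       # non-increasing times
  expect_error(drying_curve(c(0, 15), c(3, 2), 1),
               class = "dryopt_invalid_input")       # too few points
  expect_error(drying_curve(c(0, 15, 30), c(3, 2, 0.5), 1),
               class = "dryopt_invalid_input")       # mass below dry mass
})
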