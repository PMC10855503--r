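test_that("noiseless simulated curves invert to their anchor slopes", {
  anchors <- thin_layer_reference()
  temps <- anchors[anchors$sweep == "temperature", ]
  spec <- generator_spec()
  for (i in seq_len(nrow(temps))) {
    cu <- simulate_drying_curve(temperature = temps$level[i], thickness = 6,
                                distance = 120, spec = spec, noise = FALSE)
    fit <- fit_thin_layer(moisture_ratio_series(cu))
    # slopes are per 15-min weighing interval in the anchor table
    expect_equal(fit$slope * spec$interval_min, temps$slope[i],
                 tolerance = 1e-6)
  }
})

test_that("hotter runs dry faster and generation is seed repeatable", {
  times <- vapply(c(50, 55, 60, 65, 70), function(T) {
    cu <- simulate_drying_curve(temperature = T, noise = FALSE)
    max(cu$times)
  }, 0)
  expect_true(all(diff(times) <= 0))  # drying time monotone down in T

  c1 <- simulate_drying_curve(60, 6, 120, seed = 44)
  c2 <- simulate_drying_curve(60, 6, 120, seed = 44)
  expect_identical(c1$masses, c2$masses)
  c3 <- simulate_drying_curve(60, 6, 120, seed = 45)
  expect_false(identical(c1$masses, c3$masses))

  # the curve satisfies its own invariants by construction
  expect_s3_class(c1, "drying_curve")
  expect_true(all(c1$masses >= c1$dry_mass))
})

test_that("zero-noise tables reproduce the truth surfaces exactly", {
  quiet_spec <- generator_spec(cv_percent = rep(0, 6))
  tab <- simulate_bbd_table(spec = quiet_spec, seed = 1)
  truth <- reference_models()
  for (r in c("Y1", "Y4")) {
    refit <- fit_quadratic(tab, r, terms = truth[[r]]$terms)
    expect_equal(refit$coefficients[names(truth[[r]]$coefficients)],
                 truth[[r]]$coefficients, tolerance = 1e-6)
    expect_equal(refit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("refits at calibrated noise have the expected quality and recover coefficients", {
  spec <- generator_spec()
  truth <- reference_models()$Y1
  r2s <- numeric(200)
  hits <- logical(200)
  for (s in 1:200) {
    tab <- simulate_bbd_table(spec = spec, seed = 3000 + s)
    full <- fit_quadratic(tab, "Y1")
    r2s[s] <- full$r_squared
    refit <- fit_quadratic(tab, "Y1", terms = truth$terms)
    dev <- abs(refit$coefficients[names(truth$coefficients)] -
                 truth$coefficients)
    hits[s] <- all(dev <= 3 * refit$se[names(truth$coefficients)])
  }
  expect_gte(median(r2s), 0.85)
  expect_lte(median(r2s), 1.0)
  # truth coefficients inside +/- 3 SE in at least 95% of replicates
  expect_gte(mean(hits), 0.95)
})

test_that("CV weights of simulated tables center on the noiseless truth weights", {
  quiet_spec <- generator_spec(cv_percent = rep(0, 6))
  w_truth <- cv_weights(simulate_bbd_table(spec = quiet_spec, seed = 1))$weight
  spec <- generator_spec()
  W <- vapply(1:100, function(s)
    cv_weights(simulate_bbd_table(spec = spec, seed = 500 + s))$weight,
    numeric(6))
  expect_equal(rowMeans(W), w_truth, tolerance = 0.03)
})

test_that("the recovery experiment keeps recommendations in the box and near truth at low noise", {
  spec <- generator_spec(cv_percent = rep(0.5, 6))
  out <- recovery_experiment(spec, n_replicates = 2, seed = 12,
                             population = 15, iterations = 25, capacity = 20)
  recs <- out$factor_recommendations
  expect_true(all(recs$A >= 55 & recs$A <= 65))
  expect_true(all(recs$B >= 4 & recs$B <= 8))
  expect_true(all(recs$C >= 80 & recs$C <= 160))
  expect_length(out$bias, 3)
  expect_true(all(is.finite(out$spread)))
})
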