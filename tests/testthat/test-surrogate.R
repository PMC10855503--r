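test_that("fit metrics follow their definitions", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(rep(2, 4), 1:4), class = "dryopt_invalid_input")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 0.3), 0.3)
  expect_equal(rmse(y, y - 2), 2)
})

test_that("hidden-size candidates cover the scan and the additive heuristic", {
  expect_equal(hidden_node_candidates(), 3:13)
  expect_length(hidden_node_candidates(), 11)
  expect_equal(hidden_node_candidates(c(8, 8)), 8L)
  expect_error(hidden_node_candidates(c(9, 3)), class = "dryopt_invalid_input")
  # M = N + L + a with a in [0, 10] spans 4..14 for a 3-input 1-output net
  expect_equal(heuristic_hidden_nodes(3, 1, 0), 4)
  expect_equal(heuristic_hidden_nodes(3, 1, 10), 14)
  expect_error(heuristic_hidden_nodes(3, 1, 11), class = "dryopt_invalid_input")
})

test_that("surrogate training is seed-deterministic and has capacity for quadratic truth", {
  quiet_spec <- generator_spec(cv_percent = rep(0, 6))
  tab <- simulate_bbd_table(spec = quiet_spec, seed = 5)

  n1 <- train_surrogate(tab, "Y1", hidden = 8, seed = 42)
  n2 <- train_surrogate(tab, "Y1", hidden = 8, seed = 42)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$W2, n2$W2)
  expect_identical(n1$train_index, n2$train_index)

  # noiseless quadratic truth is within an 8-node net's capacity
  expect_gte(n1$metrics$all$r_squared, 0.99)

  # the best-so-far training loss is non-increasing across checkpoints
  expect_true(all(diff(n1$loss_trace) <= 0))

  # normalization round trip: predictions at the training rows come back in
  # response units, not normalized ones
  expect_equal(mean(predict(n1, tab)), mean(tab$Y1), tolerance = 0.05)
})

test_that("serialization round-trips the network exactly", {
  tab <- yam_bbd_table()
  net <- train_surrogate(tab, "Y2", hidden = 5, seed = 7, max_epochs = 3000,
                         patience = 300)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_surrogate(net, path)
  back <- read_surrogate(path)
  expect_equal(predict(back, tab), predict(net, tab), tolerance = 1e-12)
})

test_that("the hidden-size scan returns the best candidate by mean test R^2", {
  quiet_spec <- generator_spec(cv_percent = rep(0, 6))
  tab <- simulate_bbd_table(spec = quiet_spec, seed = 9)
  scan <- suppressWarnings(
    scan_hidden_nodes(tab, responses = c("Y1", "Y3"), scan = c(4, 8),
                      seed = 3, max_epochs = 4000, patience = 300))
  expect_true(scan$best_hidden %in% c(4, 8))
  expect_equal(scan$summary$hidden, c(4, 8))
  expect_equal(scan$best_hidden,
               scan$summary$hidden[which.max(scan$summary$mean_test_r2)])
  expect_named(scan$nets, c("Y1", "Y3"))
})
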