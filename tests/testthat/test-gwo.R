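test_that("the pack move reduces to the leader centroid when A vanishes", {
  X <- matrix(runif(12, 0, 10), 4, 3)
  leaders <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  Z <- matrix(0, 4, 3)
  moved <- dryopt:::gwo_move(X, leaders, Z, Z, Z, Z + 1, Z + 1, Z + 1)
  centroid <- colMeans(leaders)
  for (i in 1:4) expect_equal(moved[i, ], centroid, ignore_attr = TRUE)
})

test_that("one hand-computed 1-D update is reproduced exactly", {
  # wolf at 2; leaders at 0.5, 1.0, 1.5; all A = 0.5, all C = 1:
  # X1 = 0.5 - 0.5*|0.5-2| = -0.25; X2 = 1 - 0.5*1 = 0.5;
  # X3 = 1.5 - 0.5*0.5 = 1.25; mean = 0.5
  X <- matrix(2, 1, 1)
  leaders <- matrix(c(0.5, 1.0, 1.5), 3, 1)
  half <- matrix(0.5, 1, 1); one <- matrix(1, 1, 1)
  moved <- dryopt:::gwo_move(X, leaders, half, half, half, one, one, one)
  expect_equal(moved[1, 1], 0.5)
})

test_that("leader ranking breaks ties by lowest index", {
  expect_equal(dryopt:::leader_order(c(3, 1, 1, 2)), c(2, 3, 4, 1))
  expect_equal(dryopt:::leader_order(rep(7, 5)), 1:5)
})

test_that("gwo_minimize is reproducible, monotone, bounded and handles edge budgets", {
  bounds <- gwo_bounds(c(-5, -5, -5), c(5, 5, 5))
  sphere <- function(x) sum(x^2)
  r1 <- gwo_minimize(sphere, bounds, population = 20, iterations = 80, seed = 1)
  r2 <- gwo_minimize(sphere, bounds, population = 20, iterations = 80, seed = 1)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) <= 0))                  # best-so-far monotone
  expect_true(all(r1$par >= bounds$low & r1$par <= bounds$high))

  r0 <- gwo_minimize(sphere, bounds, population = 10, iterations = 0, seed = 2)
  expect_length(r0$trace, 0)                             # best of initial pack
  expect_true(is.finite(r0$value))

  # maximizing is minimizing the negation
  rmax <- gwo_maximize(function(x) -sphere(x), bounds, population = 20,
                       iterations = 80, seed = 1)
  expect_equal(rmax$value, -r1$value)
  expect_equal(rmax$par, r1$par)
})

test_that("positions stay inside the box through every step", {
  bounds <- gwo_bounds(c(0, 0), c(1, 2))
  state <- list(positions = matrix(runif(20), 10, 2), iteration = 0L,
                max_iterations = 50L)
  obj <- function(x) (x[1] - 0.3)^2 + (x[2] - 1.5)^2
  state$fitness <- apply(state$positions, 1, obj)
  set.seed(33)
  for (k in 1:50) {
    state <- gwo_step(state, obj, bounds)
    expect_true(all(state$positions >= 0))
    expect_true(all(state$positions[, 1] <= 1 & state$positions[, 2] <= 2))
  }
})
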