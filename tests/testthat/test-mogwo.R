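test_that("dominance is direction-aware and matches the brute-force oracle", {
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_true(dominates(c(1, 1), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 1)))
  # maximize flips the comparison
  expect_true(dominates(c(2, 2), c(1, 2), directions = rep("maximize", 2)))

  set.seed(21)
  M <- matrix(sample(1:5, 50 * 3, replace = TRUE), 50, 3)
  for (i in 1:50) for (j in 1:50) {
    if (i == j) next
    expect_identical(dominates(M[i, ], M[j, ]),
                     brute_dominates(M[i, ], M[j, ]))
  }
  expect_error(dominates(c(1, 2), c(1, 2, 3)), class = "dryopt_invalid_input")
})

test_that("archive updates preserve mutual non-dominance and the capacity bound", {
  arch <- pareto_archive(2, 2, capacity = 15)
  set.seed(8)
  for (round in 1:6) {
    P <- matrix(runif(40), 20, 2)
    O <- cbind(P[, 1]^2 + 0.1 * runif(20), (P[, 1] - 1)^2 + 0.1 * runif(20))
    arch <- archive_update(arch, P, O)
    expect_lte(nrow(arch$objectives), 15)
    keep <- brute_nondominated(arch$objectives)
    expect_true(all(keep))   # no member dominates another, brute-force checked
  }
  # a point dominating everything collapses the archive to itself
  arch2 <- archive_update(arch, matrix(0.5, 1, 2), matrix(c(-1, -1), 1, 2))
  expect_equal(nrow(arch2$objectives), 1)
  expect_equal(arch2$objectives[1, ], c(-1, -1))
  # a dominated candidate changes nothing
  arch3 <- archive_update(arch2, matrix(0.1, 1, 2), matrix(c(5, 5), 1, 2))
  expect_equal(arch3$objectives, arch2$objectives)
})

test_that("mogwo reduces to single-objective search and is seed reproducible", {
  bounds <- gwo_bounds(c(-4, -4), c(4, 4))
  obj <- function(x) sum((x - c(1, -2))^2)
  a1 <- mogwo(function(x) obj(x), directions = "minimize", bounds = bounds,
              population = 25, capacity = 20, iterations = 120, seed = 5)
  expect_lte(nrow(a1$objectives), 2)  # near-singleton: one non-dominated value
  g <- gwo_minimize(obj, bounds, population = 25, iterations = 120, seed = 5)
  expect_lt(min(a1$objectives), g$value + 0.05)

  a2 <- mogwo(function(x) obj(x), directions = "minimize", bounds = bounds,
              population = 25, capacity = 20, iterations = 120, seed = 5)
  expect_identical(a1$positions, a2$positions)
  expect_identical(a1$objectives, a2$objectives)
})

test_that("mogwo recovers a convex two-objective front (hypervolume oracle)", {
  # f1 = x^2, f2 = (x-2)^2 on x in [-1, 3]: the Pareto set is x in [0, 2]
  bounds <- gwo_bounds(-1, 3)
  fn <- function(x) c(x[1]^2, (x[1] - 2)^2)
  ref <- c(5, 5)
  xs <- seq(0, 2, length.out = 4001)
  hv_true <- hypervolume_2d(cbind(xs^2, (xs - 2)^2), ref)
  for (s in c(2, 7, 19)) {
    arch <- mogwo(fn, directions = rep("minimize", 2), bounds = bounds,
                  population = 30, capacity = 60, iterations = 150, seed = s)
    hv <- hypervolume_2d(arch$objectives, ref)
    expect_gt(hv / hv_true, 0.98)
    expect_lte(hv / hv_true, 1 + 1e-9)
  }
})

test_that("archive members of the drying search stay within the attainable response ranges", {
  models <- reference_models()
  arch <- mogwo(models, population = 40, capacity = 60, iterations = 120,
                seed = 11)
  # attainable range oracle: each model's min/max over a dense grid of the box
  g <- expand.grid(A = seq(55, 65, length.out = 41),
                   B = seq(4, 8, length.out = 41),
                   C = seq(80, 160, length.out = 41))
  for (j in seq_along(models)) {
    rng <- range(predict(models[[j]], g, extrapolation_warning = FALSE))
    expect_true(all(arch$objectives[, j] >= rng[1] - 1e-6))
    expect_true(all(arch$objectives[, j] <= rng[2] + 1e-6))
  }
  # positions respect the box
  expect_true(all(arch$positions >= matrix(c(55, 4, 80), nrow(arch$positions),
                                           3, byrow = TRUE)))
  expect_true(all(arch$positions <= matrix(c(65, 8, 160), nrow(arch$positions),
                                           3, byrow = TRUE)))
})

test_that("Pareto selection averages the k best compromise solutions", {
  spec <- reference_fitness_spec()
  ps <- pareto_reference()
  # column means match an independent summation
  rec <- pareto_select_average(ps, spec, k = 10)
  for (col in c("A", "B", "C"))
    expect_equal(unname(rec$factors[col]), sum(ps[[col]]) / nrow(ps),
                 tolerance = 1e-12)
  # identical members average to themselves
  same <- ps[rep(1, 12), ]
  rec1 <- pareto_select_average(same, spec, k = 10)
  expect_equal(unname(rec1$factors), unlist(ps[1, c("A", "B", "C")]),
               ignore_attr = TRUE)
  # asking for more members than exist warns and uses all
  expect_warning(pareto_select_average(ps[1:4, ], spec, k = 10), "using all")
})
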