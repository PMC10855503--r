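test_that("Box-Behnken design has the canonical 12 + 5 structure", {
  d <- bbd_design()
  expect_equal(nrow(d), 17)
  expect_equal(unlist(d[1, c("A", "B", "C")], use.names = FALSE), c(55, 4, 120))
  expect_equal(unlist(d[1, c("cA", "cB", "cC")], use.names = FALSE), c(-1, -1, 0))
  coded <- as.matrix(d[c("cA", "cB", "cC")])
  expect_true(all(colSums(coded) == 0))             # design balance
  expect_equal(sum(rowSums(coded == 0) == 3), 5)    # five center replicates
  expect_true(all(coded %in% c(-1, 0, 1)))
  # coding map is invertible
  expect_equal(decode_factors(factor_space(), code_factors(factor_space(), d)),
               d[c("A", "B", "C")], ignore_attr = TRUE)
})

test_that("quadratic OLS matches the normal-equations oracle and recovers exact surfaces", {
  tab <- yam_bbd_table()
  fit <- fit_quadratic(tab, "Y1")
  X <- oracle_design(tab$A, tab$B, tab$C)
  beta <- ols_oracle(X, tab$Y1)
  # oracle column order: 1, A, B, C, AB, AC, BC, A2, B2, C2
  expect_equal(unname(fit$coefficients[c("(Intercept)", "A", "B", "C", "AB",
                                         "AC", "BC", "A2", "B2", "C2")]),
               beta, tolerance = 1e-10)

  # exact quadratic data comes back with zero residuals
  d <- bbd_design()
  truth <- 10 + 2 * d$A - 0.5 * d$B + 0.01 * d$C + 0.03 * d$A * d$C - 0.02 * d$A^2
  d$Y <- truth
  exact <- fit_quadratic(d, "Y")
  expect_lt(max(abs(exact$residuals)), 1e-9)
  expect_equal(unname(exact$coefficients[c("A", "B", "C", "AC", "A2")]),
               c(2, -0.5, 0.01, 0.03, -0.02), tolerance = 1e-9)

  # coded and actual parameterizations predict identically at the design points
  fc <- fit_quadratic(tab, "Y1", parameterization = "coded")
  expect_equal(predict(fit, tab), predict(fc, tab), tolerance = 1e-9)

  # residuals orthogonal to every standardized model column
  Xs <- scale(X[, -1])
  expect_lt(max(abs(t(Xs) %*% fit$residuals)), 1e-6)

  expect_error(fit_quadratic(tab[1:5, ], "Y1"), class = "dryopt_invalid_input")
})

test_that("ANOVA decomposes sums of squares exactly and flags missing replication", {
  tab <- yam_bbd_table()
  for (r in c("Y1", "Y5")) {
    m <- fit_quadratic(tab, r)
    a <- rsm_anova(m)
    # SST = SSR + SSE and SSE = SS_lof + SS_pe
    expect_equal(a$total$ss, a$model$ss + a$residual$ss,
                 tolerance = 1e-8 * a$total$ss)
    expect_equal(a$residual$ss, a$lack_of_fit$ss + a$pure_error$ss,
                 tolerance = 1e-8 * max(a$residual$ss, 1))
    # degrees of freedom: 9 model + 7 residual = 16 total; 3 lof + 4 pure
    expect_equal(a$model$df + a$residual$df, a$total$df)
    expect_equal(a$total$df, 16)
    expect_equal(a$lack_of_fit$df, 3)
    expect_equal(a$pure_error$df, 4)
  }
  # without replicated runs the lack-of-fit split is unavailable
  d <- bbd_design(center_replicates = 1)
  d$Y <- 5 + d$A + stats::rnorm(nrow(d))
  m1 <- fit_quadratic(d, "Y")
  expect_warning(a1 <- rsm_anova(m1), "lack-of-fit")
  expect_true(is.na(a1$lack_of_fit$f))
})

test_that("pruning keeps exactly the significant terms and never raises R^2", {
  tab <- yam_bbd_table()
  expected_terms <- list(
    Y1 = c("A", "B", "C", "AC", "BC"),
    Y3 = c("A", "B", "C", "A2"))
  for (r in names(expected_terms)) {
    m <- fit_quadratic(tab, r)
    p <- prune_model(m)
    expect_setequal(p$terms, expected_terms[[r]])
    expect_lte(p$r_squared, m$r_squared)
  }
  # alpha = 1 keeps everything
  m <- fit_quadratic(tab, "Y2")
  expect_setequal(prune_model(m, alpha = 1)$terms, quad_terms())
  # all-insignificant case collapses to the intercept with a warning
  set.seed(2)
  d <- bbd_design()
  d$Y <- rnorm(17, 100, 1)
  expect_warning(p0 <- prune_model(fit_quadratic(d, "Y"), alpha = 1e-6),
                 "intercept-only")
  expect_equal(unname(p0$coefficients["(Intercept)"]), mean(d$Y))
})

test_that("prediction evaluates the polynomial and warns on extrapolation", {
  # published reduced drying-time equation at the center point
  m <- reference_models()$Y1
  expect_equal(predict(m, data.frame(A = 60, B = 6, C = 120)), 207.35,
               tolerance = 1e-4)
  m0 <- quadratic_model(c(`(Intercept)` = 4.2))
  expect_equal(predict(m0, data.frame(A = 58, B = 5, C = 100)), 4.2)
  expect_warning(predict(m, data.frame(A = 70, B = 6, C = 120)),
                 "extrapolation")
})
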