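#' Box bounds for the optimizer
#'
#' @param low,high Numeric vectors of equal length with `low < high`
#'   elementwise. Defaults are the drying-process box: temperature 55-65
#'   degC, thickness 4-8 mm, radiation distance 80-160 mm.
#' @return Object of class `gwo_bounds`.
#' @export
gwo_bounds <- function(low = c(55, 4, 80), high = c(65, 8, 160)) {
  if (length(low) != length(high) || any(low >= high))
    stop_invalid("bounds need `low < high` in every dimension")
  structure(list(low = as.numeric(low), high = as.numeric(high)),
            class = "gwo_bounds")
}

clip_to_bounds <- function(X, bounds) {
  X <- pmax(X, matrix(bounds$low, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(bounds$high, nrow(X), ncol(X), byrow = TRUE))
}

# Deterministic core of one pack move: given the three leader positions and
# the already-drawn coefficient matrices A_i, C_i (one row per wolf), each
# wolf's new position is the mean of the three leader-guided points
# X_i = X_leader - A_i * |C_i * X_leader - X|.
gwo_move <- function(X, leaders, A1, A2, A3, C1, C2, C3) {
  n <- nrow(X); d <- ncol(X)
  La <- matrix(leaders[1, ], n, d, byrow = TRUE)
  Lb <- matrix(leaders[2, ], n, d, byrow = TRUE)
  Ld <- matrix(leaders[3, ], n, d, byrow = TRUE)
  X1 <- La - A1 * abs(C1 * La - X)
  X2 <- Lb - A2 * abs(C2 * Lb - X)
  X3 <- Ld - A3 * abs(C3 * Ld - X)
  (X1 + X2 + X3) / 3
}

rand_coef <- function(n, d, a) {
  r1 <- matrix(stats::runif(n * d), n, d)
  list(A = 2 * a * r1 - a, C = 2 * matrix(stats::runif(n * d), n, d))
}

# Rank rows by fitness with a stable (lowest index first) tie-break.
leader_order <- function(fitness) order(fitness, seq_along(fitness))

#' One iteration of the Grey Wolf Optimizer
#'
#' Moves every wolf toward a stochastic combination of the three current
#' leaders (alpha, beta, delta), using the exploration coefficient
#' `a = 2 (1 - k / k_max)` that decays linearly from 2 to 0 over the run.
#' New positions are clipped to the box, candidates with non-finite
#' objective values keep their previous position, and the leaders are
#' re-ranked (ties broken by lowest index).
#'
#' @param state List with `positions` (matrix, one row per wolf), `fitness`,
#'   `iteration` and `max_iterations`, as produced internally by
#'   [gwo_minimize()].
#' @param objective Function of a numeric vector returning a scalar to
#'   minimize.
#' @param bounds A [gwo_bounds()].
#' @return Updated state.
#' @export
gwo_step <- function(state, objective, bounds) {
  X <- state$positions
  n <- nrow(X); d <- ncol(X)
  if (n < 3) stop_invalid("the pack needs at least 3 wolves")
  a <- 2 * (1 - state$iteration / state$max_iterations)
  ord <- leader_order(state$fitness)
  leaders <- X[ord[1:3], , drop = FALSE]
  c1 <- rand_coef(n, d, a); c2 <- rand_coef(n, d, a); c3 <- rand_coef(n, d, a)
  Xn <- clip_to_bounds(
    gwo_move(X, leaders, c1$A, c2$A, c3$A, c1$C, c2$C, c3$C), bounds)
  fn <- apply(Xn, 1, objective)
  bad <- !is.finite(fn)
  if (any(bad)) { Xn[bad, ] <- X[bad, ]; fn[bad] <- state$fitness[bad] }
  state$positions <- Xn
  state$fitness <- fn
  state$iteration <- state$iteration + 1L
  state
}

#' Minimize an objective over a box with the Grey Wolf Optimizer
#'
#' Population metaheuristic: candidate solutions ("wolves") iteratively move
#' toward the equally weighted combination of the three best solutions found
#' so far, with an exploration radius that decays linearly across
#' iterations. Fully reproducible for a fixed seed.
#'
#' @param objective Function of a numeric vector returning a finite scalar.
#' @param bounds A [gwo_bounds()].
#' @param population Pack size (default 100).
#' @param iterations Number of iterations (default 1000).
#' @param seed Integer seed; `NULL` uses the session RNG stream.
#' @return Object of class `gwo_result`: `par`, `value`, the monotone
#'   best-so-far `trace`, and the settings used.
#' @export
gwo_minimize <- function(objective, bounds, population = 100,
                         iterations = 1000, seed = NULL) {
  stopifnot(inherits(bounds, "gwo_bounds"))
  d <- length(bounds$low)
  with_seed(seed, {
    X <- matrix(stats::runif(population * d), population, d)
    X <- sweep(sweep(X, 2, bounds$high - bounds$low, "*"), 2, bounds$low, "+")
    fit <- apply(X, 1, objective)
    if (any(!is.finite(fit)))
      stop_invalid("objective non-finite on initial population")
    state <- list(positions = X, fitness = fit, iteration = 0L,
                  max_iterations = max(1L, iterations))
    i_best <- leader_order(fit)[1]
    best_par <- X[i_best, ]; best_val <- fit[i_best]
    trace <- numeric(iterations)
    k <- 0L
    while (k < iterations) {
      state <- gwo_step(state, objective, bounds)
      k <- k + 1L
      i <- leader_order(state$fitness)[1]
      if (state$fitness[i] < best_val) {
        best_val <- state$fitness[i]; best_par <- state$positions[i, ]
      }
      trace[k] <- best_val
    }
    structure(list(par = best_par, value = best_val, trace = trace,
                   settings = list(population = population,
                                   iterations = iterations, seed = seed)),
              class = "gwo_result")
  })
}

#' @rdname gwo_minimize
#' @export
gwo_maximize <- function(objective, bounds, population = 100,
                         iterations = 1000, seed = NULL) {
  res <- gwo_minimize(function(x) -objective(x), bounds,
                      population = population, iterations = iterations,
                      seed = seed)
  res$value <- -res$value
  res$trace <- -res$trace
  res
}

#' @export
print.gwo_result <- function(x, ...) {
  cat(sprintf("<gwo_result> value %.6g at (%s)\n", x$value,
              paste(signif(x$par, 6), collapse = ", ")))
  invisible(x)
}
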