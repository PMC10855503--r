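# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: OLS by explicit normal equations, dominance by
# exhaustive coordinate comparison, hypervolume by rectangle summation.

# Two-pass normal-equations OLS: coefficients from solve(X'X, X'y).
ols_oracle <- function(X, y) {
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# Exhaustive dominance check (all-minimize scale).
brute_dominates <- function(u, v) {
  better_or_equal <- TRUE
  strictly <- FALSE
  for (i in seq_along(u)) {
    if (u[i] > v[i]) better_or_equal <- FALSE
    if (u[i] < v[i]) strictly <- TRUE
  }
  better_or_equal && strictly
}

# Flags of mutually non-dominated rows by brute force (all-minimize scale).
brute_nondominated <- function(M) {
  n <- nrow(M)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && brute_dominates(M[j, ], M[i, ])) keep[i] <- FALSE
  keep
}

# 2-D hypervolume (minimization) of a point set against a reference corner.
hypervolume_2d <- function(points, ref) {
  pts <- points[points[, 1] <= ref[1] & points[, 2] <= ref[2], , drop = FALSE]
  keep <- brute_nondominated(pts)
  pts <- pts[keep, , drop = FALSE]
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  hv <- 0
  prev_f2 <- ref[2]
  for (i in seq_len(nrow(pts))) {
    hv <- hv + (ref[1] - pts[i, 1]) * (prev_f2 - pts[i, 2])
    prev_f2 <- pts[i, 2]
  }
  hv
}

# Full quadratic design columns for the oracle fits (mirrors the canonical
# term order but is written independently of the package).
oracle_design <- function(A, B, C) {
  cbind(1, A, B, C, A * B, A * C, B * C, A^2, B^2, C^2)
}
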