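# Direction handling: objectives are stored on their natural scale; internal
# comparisons flip maximized coordinates so that "smaller is better"
# everywhere.
direction_signs <- function(directions) {
  directions <- match.arg(directions, c("minimize", "maximize"),
                          several.ok = TRUE)
  ifelse(directions == "minimize", 1, -1)
}

#' Pareto dominance between two objective vectors
#'
#' `u` dominates `v` when `u` is at least as good in every coordinate
#' (respecting each coordinate's optimization direction) and strictly
#' better in at least one. A vector never dominates itself.
#'
#' @param u,v Equal-length numeric objective vectors.
#' @param directions Per-coordinate `"minimize"`/`"maximize"`.
#' @return Logical scalar.
#' @export
dominates <- function(u, v, directions = rep("minimize", length(u))) {
  if (length(u) != length(v)) stop_invalid("objective vectors differ in length")
  s <- direction_signs(directions)
  du <- s * u; dv <- s * v
  all(du <= dv) && any(du < dv)
}

# Keep-flags for the mutually non-dominated subset of a minimized-scale
# objective matrix. Exact duplicate rows keep only their first occurrence.
non_dominated <- function(M) {
  n <- nrow(M)
  keep <- rep(TRUE, n)
  dup <- duplicated(M)
  keep[dup] <- FALSE
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])) { keep[i] <- FALSE; break }
    }
  }
  keep
}

#' Create an empty Pareto archive
#'
#' Capacity-bounded store of mutually non-dominated (position, objective)
#' pairs. Crowding control uses an adaptive hypercube grid over objective
#' space with `n_grid` divisions per objective: overflow is resolved by
#' deleting members from the most crowded cells, and leaders are drawn from
#' sparsely populated cells.
#'
#' @param n_objectives Number of objectives.
#' @param n_dims Decision-space dimension.
#' @param directions Per-objective optimization direction.
#' @param capacity Maximum number of stored members (default 100).
#' @param n_grid Grid divisions per objective (default 10).
#' @return Object of class `pareto_archive`.
#' @export
pareto_archive <- function(n_objectives, n_dims,
                           directions = rep("minimize", n_objectives),
                           capacity = 100, n_grid = 10) {
  if (length(directions) != n_objectives)
    stop_invalid("one direction per objective required")
  structure(
    list(positions = matrix(numeric(0), 0, n_dims),
         objectives = matrix(numeric(0), 0, n_objectives),
         directions = directions, capacity = capacity, n_grid = n_grid),
    class = "pareto_archive")
}

archive_size <- function(archive) nrow(archive$objectives)

# Hypercube cell index (single integer) per member on the minimized scale.
archive_cells <- function(M_min, n_grid) {
  n <- nrow(M_min); m <- ncol(M_min)
  cell <- integer(n)
  for (j in seq_len(m)) {
    lo <- min(M_min[, j]); hi <- max(M_min[, j])
    idx <- if (hi > lo)
      pmin(n_grid - 1L, floor((M_min[, j] - lo) / (hi - lo) * n_grid))
    else rep(0L, n)
    cell <- cell * n_grid + as.integer(idx)
  }
  cell
}

#' Update a Pareto archive with candidate solutions
#'
#' Inserts candidates, removes every dominated member, and if the archive
#' then exceeds its capacity deletes members one at a time from the most
#' crowded hypercube grid cell (random member within the cell) until the
#' capacity holds.
#'
#' @param archive A [pareto_archive()].
#' @param positions Matrix of candidate positions (one row each).
#' @param objectives Matrix of candidate objective vectors (natural scale).
#' @return The updated archive.
#' @export
archive_update <- function(archive, positions, objectives) {
  stopifnot(inherits(archive, "pareto_archive"))
  positions <- rbind(archive$positions, positions)
  objectives <- rbind(archive$objectives, objectives)
  s <- direction_signs(archive$directions)
  M <- sweep(objectives, 2, s, "*")
  keep <- non_dominated(M)
  positions <- positions[keep, , drop = FALSE]
  objectives <- objectives[keep, , drop = FALSE]
  M <- M[keep, , drop = FALSE]
  while (nrow(objectives) > archive$capacity) {
    cells <- archive_cells(M, archive$n_grid)
    counts <- table(cells)
    crowded <- names(counts)[which.max(counts)]
    members <- which(cells == as.integer(crowded))
    drop_i <- members[sample.int(length(members), 1)]
    positions <- positions[-drop_i, , drop = FALSE]
    objectives <- objectives[-drop_i, , drop = FALSE]
    M <- M[-drop_i, , drop = FALSE]
  }
  archive$positions <- positions
  archive$objectives <- objectives
  archive
}

# Roulette selection of three leader positions from sparse grid cells:
# cell selection probability is inversely proportional to occupancy, then a
# uniform member of the cell. Falls back to resampling members when the
# archive holds fewer than 3 points.
archive_select_leaders <- function(archive) {
  n <- archive_size(archive)
  if (n == 0) stop("empty archive: no leaders available")
  if (n <= 3) {
    idx <- rep_len(sample.int(n), 3)
    return(archive$positions[idx, , drop = FALSE])
  }
  s <- direction_signs(archive$directions)
  M <- sweep(archive$objectives, 2, s, "*")
  cells <- archive_cells(M, archive$n_grid)
  counts <- table(cells)
  idx <- integer(3)
  pool <- seq_len(n)
  for (l in 1:3) {
    avail <- setdiff(pool, idx[seq_len(l - 1)])
    w <- 1 / as.numeric(counts[as.character(cells[avail])])
    pick <- if (length(avail) == 1) avail else
      avail[sample.int(length(avail), 1, prob = w)]
    idx[l] <- pick
  }
  archive$positions[idx, , drop = FALSE]
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("<pareto_archive> %d / %d members, %d objectives\n",
              archive_size(x), x$capacity, length(x$directions)))
  invisible(x)
}

#' Coerce a Pareto archive to a data frame
#'
#' @param x A `pareto_archive`.
#' @param factor_names,objective_names Column names for positions and
#'   objectives.
#' @param ... Unused.
#' @return Data frame with one row per archive member.
#' @export
as.data.frame.pareto_archive <- function(x, ...,
                                         factor_names = NULL,
                                         objective_names = NULL) {
  d <- ncol(x$positions); m <- ncol(x$objectives)
  if (is.null(factor_names)) factor_names <- paste0("x", seq_len(d))
  if (is.null(objective_names)) objective_names <- paste0("f", seq_len(m))
  out <- cbind(as.data.frame(x$positions), as.data.frame(x$objectives))
  names(out) <- c(factor_names, objective_names)
  out
}

# Normalize the `objectives` argument of mogwo() into one vector-valued
# function. Accepts a function, or a list whose elements are functions or
# model objects with a predict method over the factor space.
as_objective_fn <- function(objectives, factor_names) {
  if (is.function(objectives)) return(objectives)
  stopifnot(is.list(objectives), length(objectives) >= 1)
  evals <- lapply(objectives, function(o) {
    if (is.function(o)) return(o)
    function(x) {
      nd <- as.data.frame(as.list(stats::setNames(x, factor_names)))
      as.numeric(stats::predict(o, nd, extrapolation_warning = FALSE))
    }
  })
  function(x) vapply(evals, function(f) f(x), 0)
}

# Batched variant: maps a whole pack (matrix, one position per row) to the
# objective matrix in one predict call per model.
as_batch_objective_fn <- function(objectives, factor_names) {
  if (is.function(objectives))
    return(function(X) {
      res <- apply(X, 1, objectives)
      if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
    })
  stopifnot(is.list(objectives), length(objectives) >= 1)
  function(X) {
    df <- as.data.frame(X)
    names(df) <- factor_names[seq_len(ncol(X))]
    out <- vapply(objectives, function(o) {
      if (is.function(o)) apply(X, 1, o)
      else as.numeric(stats::predict(o, df, extrapolation_warning = FALSE))
    }, numeric(nrow(X)))
    matrix(out, nrow = nrow(X))
  }
}

objective_factor_names <- function(objectives, d) {
  if (!is.function(objectives) && is.list(objectives)) {
    first <- objectives[[1]]
    if (inherits(first, "quadratic_model") || inherits(first, "surrogate_net"))
      return(first$space$names)
  }
  paste0("x", seq_len(d))
}

#' Multi-objective Grey Wolf Optimization
#'
#' Archive-based multi-objective variant: the pack moves exactly as in
#' [gwo_minimize()], but the three leaders are drawn each iteration from the
#' external archive of non-dominated solutions (roulette over sparse
#' hypercube cells), and every evaluated pack is offered to the archive.
#'
#' @param objectives A function mapping a position to a numeric objective
#'   vector, or a list of per-objective functions / predictable models.
#' @param directions Per-objective `"minimize"`/`"maximize"`. Default: the
#'   drying study's layout — minimize the first three indicators, maximize
#'   the last three.
#' @param bounds A [gwo_bounds()].
#' @param population Pack size (default 100).
#' @param capacity Archive capacity (default 100).
#' @param iterations Iteration count (default 1000).
#' @param seed Integer seed for full reproducibility.
#' @param n_grid Hypercube divisions per objective (default 10).
#' @return The final [pareto_archive()].
#' @export
mogwo <- function(objectives,
                  directions = c(rep("minimize", 3), rep("maximize", 3)),
                  bounds = gwo_bounds(), population = 100, capacity = 100,
                  iterations = 1000, seed = NULL, n_grid = 10) {
  stopifnot(inherits(bounds, "gwo_bounds"))
  d <- length(bounds$low)
  fn <- as_batch_objective_fn(objectives, objective_factor_names(objectives, d))
  with_seed(seed, {
    X <- matrix(stats::runif(population * d), population, d)
    X <- sweep(sweep(X, 2, bounds$high - bounds$low, "*"), 2, bounds$low, "+")
    F0 <- fn(X)
    m <- ncol(F0)
    if (length(directions) != m)
      stop_invalid("one direction per objective required")
    archive <- pareto_archive(m, d, directions, capacity, n_grid)
    archive <- archive_update(archive, X, F0)
    if (archive_size(archive) == 0) stop("empty archive after initialization")
    for (k in seq_len(iterations)) {
      a <- 2 * (1 - k / iterations)
      leaders <- archive_select_leaders(archive)
      c1 <- rand_coef(population, d, a)
      c2 <- rand_coef(population, d, a)
      c3 <- rand_coef(population, d, a)
      X <- clip_to_bounds(
        gwo_move(X, leaders, c1$A, c2$A, c3$A, c1$C, c2$C, c3$C), bounds)
      Fk <- fn(X)
      ok <- apply(is.finite(Fk), 1, all)
      archive <- archive_update(archive, X[ok, , drop = FALSE],
                                Fk[ok, , drop = FALSE])
    }
    archive
  })
}

#' Select and average the best compromise solutions of a Pareto set
#'
#' Ranks the members by the composite scalarized fitness (see
#' [composite_fitness()]), takes the `k` best, and averages their factor
#' coordinates and objective vectors coordinate-wise. This replaces a
#' by-eye pick of clustered solutions with a documented, reproducible rule.
#'
#' @param solutions A `pareto_archive`, or a data frame whose columns split
#'   into `factor_cols` and `response_cols`.
#' @param spec A [fitness_spec()] aligned with the objective columns.
#' @param k Number of solutions to average (default 10). Fewer available
#'   members are used in full, with a warning.
#' @param factor_cols,response_cols Column names when `solutions` is a
#'   data frame.
#' @return List with `factors` (averaged settings), `responses` (averaged
#'   predicted indicators), `fitness` of each selected member and the
#'   `selected` rows themselves.
#' @export
pareto_select_average <- function(solutions, spec, k = 10,
                                  factor_cols = c("A", "B", "C"),
                                  response_cols = paste0("Y", 1:6)) {
  if (inherits(solutions, "pareto_archive")) {
    df <- as.data.frame(solutions, factor_names = factor_cols,
                        objective_names = response_cols)
  } else {
    df <- as.data.frame(solutions)
    stopifnot(all(c(factor_cols, response_cols) %in% names(df)))
  }
  n <- nrow(df)
  if (n == 0) stop_invalid("no solutions to select from")
  if (n < k) {
    warning(sprintf("only %d solutions available; using all", n))
    k <- n
  }
  fit <- apply(as.matrix(df[response_cols]), 1, composite_fitness, spec = spec)
  sel <- order(fit, seq_len(n))[seq_len(k)]
  picked <- df[sel, , drop = FALSE]
  list(factors = colMeans(picked[factor_cols]),
       responses = colMeans(picked[response_cols]),
       fitness = fit[sel], selected = picked)
}
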