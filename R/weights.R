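#' Coefficient-of-variation indicator weights
#'
#' Weights each quality indicator by how much it varies across the
#' experimental runs: `V_i = sigma_i / mean_i` with the population
#' (divide-by-n) standard deviation, then `W_i = V_i / sum(V)`. Indicators
#' that discriminate more between process settings get more weight; the
#' scheme is scale-invariant per indicator. The population SD (not the
#' n-1 sample SD) is this package's convention for CV weighting.
#'
#' @param table Data frame holding the response columns.
#' @param responses Names of the indicator columns (default `Y1`..`Y6`).
#' @return Object of class `cv_weights`: data frame with `indicator`, `sd`,
#'   `mean`, `cv` and `weight` (weights sum to 1).
#' @export
cv_weights <- function(table, responses = paste0("Y", 1:6)) {
  stopifnot(is.data.frame(table), all(responses %in% names(table)))
  mns <- vapply(table[responses], mean, 0)
  if (any(mns == 0)) stop_invalid("response column with zero mean")
  sds <- vapply(table[responses], function(x) sqrt(mean((x - mean(x))^2)), 0)
  cv <- sds / abs(mns)
  if (sum(cv) == 0) stop_invalid("all responses constant: CV weights undefined")
  out <- data.frame(indicator = responses, sd = unname(sds), mean = unname(mns),
                    cv = unname(cv), weight = unname(cv / sum(cv)))
  class(out) <- c("cv_weights", "data.frame")
  out
}

#' Normalize an indicator value against its single-objective best
#'
#' For smaller-is-better indicators `k = f_best / f_act`; for
#' larger-is-better ones `k = f_act / f_best`. Either way `k = 1` at the
#' best value and `k < 1` for worse values; `k > 1` is possible when a
#' candidate beats the recorded best and is handled smoothly downstream
#' (no clamping).
#'
#' @param f_act Actual indicator value (> 0).
#' @param f_best Best value from single-objective optimization (> 0).
#' @param direction `"minimize"` or `"maximize"`.
#' @return Normalized score `k > 0`.
#' @export
normalize_indicator <- function(f_act, f_best,
                                direction = c("minimize", "maximize")) {
  direction <- match.arg(direction)
  check_number(f_act, "f_act", positive = TRUE)
  check_number(f_best, "f_best", positive = TRUE)
  if (direction == "minimize") f_best / f_act else f_act / f_best
}

#' Specification of the composite fitness
#'
#' Bundles the per-indicator weights, optimization directions and
#' single-objective best values that define the scalarized objective
#' `f = sum_i w_i (1 - k_i)^2`.
#'
#' @param weights Non-negative weights, one per indicator.
#' @param directions Character vector of `"minimize"`/`"maximize"`.
#' @param best_values Single-objective optima per indicator (> 0).
#' @param indicators Indicator labels.
#' @return Object of class `fitness_spec`.
#' @export
fitness_spec <- function(weights, directions, best_values,
                         indicators = paste0("Y", seq_along(weights))) {
  n <- length(weights)
  if (length(directions) != n || length(best_values) != n)
    stop_invalid("weights, directions and best_values must align")
  if (any(weights < 0)) stop_invalid("weights must be non-negative")
  check_number(best_values, "best_values", positive = TRUE)
  directions <- match.arg(directions, c("minimize", "maximize"),
                          several.ok = TRUE)
  structure(list(weights = weights, directions = directions,
                 best_values = best_values, indicators = indicators),
            class = "fitness_spec")
}

#' Composite scalarized fitness
#'
#' `f = sum_i w_i (1 - k_i)^2` where each `k_i` is the indicator value
#' normalized against its single-objective best (see
#' [normalize_indicator()]). `f = 0` exactly when every indicator sits at
#' its best value; any departure in any indicator increases `f`.
#'
#' @param values Indicator values (all > 0), aligned with `spec`.
#' @param spec A [fitness_spec()].
#' @return Non-negative scalar fitness.
#' @export
composite_fitness <- function(values, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (length(values) != length(spec$weights))
    stop_invalid("values do not match the fitness spec dimension")
  check_number(values, "values", positive = TRUE)
  k <- mapply(normalize_indicator, values, spec$best_values, spec$directions)
  sum(spec$weights * (1 - k)^2)
}
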