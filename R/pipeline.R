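#' Configuration of an end-to-end pipeline run
#'
#' Collects every knob of the analysis in one validated object. All
#' stochastic stages derive their seeds from `seed`, so two runs with the
#' same configuration are identical.
#'
#' @param table Response table (default: the shipped 17-run experiment).
#' @param alpha Significance threshold for model pruning.
#' @param weights_source `"computed"` (CV weights from `table`) or
#'   `"reference"` (the shipped weight table).
#' @param objective_source Which models the optimizer searches:
#'   `"rsm-full"` (full 10-term refits), `"rsm-reduced"` (pruned refits),
#'   `"reference-equations"` (the shipped reduced coefficients) or
#'   `"surrogate"` (neural surrogates trained on `table`).
#' @param best_source `"reference"` single-objective bests, or
#'   `"optimize"` to recompute them with the single-objective optimizer.
#' @param population,capacity,iterations Multi-objective optimizer settings.
#' @param k_select Number of Pareto members averaged into the
#'   recommendation.
#' @param surrogate_hidden Hidden-layer size when
#'   `objective_source = "surrogate"`.
#' @param seed Master seed.
#' @param out_dir Optional directory for CSV/JSON reports.
#' @param space The [factor_space()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(table = yam_bbd_table(), alpha = 0.05,
                            weights_source = c("computed", "reference"),
                            objective_source = c("rsm-full", "rsm-reduced",
                                                 "reference-equations",
                                                 "surrogate"),
                            best_source = c("reference", "optimize"),
                            population = 100, capacity = 100,
                            iterations = 1000, k_select = 10,
                            surrogate_hidden = 8, seed = 1, out_dir = NULL,
                            space = factor_space()) {
  structure(
    list(table = table, alpha = alpha,
         weights_source = match.arg(weights_source),
         objective_source = match.arg(objective_source),
         best_source = match.arg(best_source),
         population = population, capacity = capacity,
         iterations = iterations, k_select = k_select,
         surrogate_hidden = surrogate_hidden, seed = seed,
         out_dir = out_dir, space = space),
    class = "pipeline_config")
}

pipeline_directions <- function() c(rep("minimize", 3), rep("maximize", 3))

#' Run the full drying-optimization pipeline
#'
#' Stages: (1) fit the six full quadratic response-surface models with
#' ANOVA and prune them at `alpha`; (2) derive indicator weights;
#' (3) assemble the optimizer objectives per `objective_source`;
#' (4) obtain single-objective bests and build the composite fitness;
#' (5) run the multi-objective grey wolf search; (6) select and average the
#' best compromise solutions into a recommended operating point. Reports
#' are written to `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List with `models`, `anovas`, `pruned`, `weights`, `spec`
#'   (composite fitness), `archive`, `recommendation` and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  tab <- config$table
  responses <- paste0("Y", 1:6)
  space <- config$space

  say("[rsm] fitting %d response-surface models", length(responses))
  models <- lapply(responses, function(r)
    fit_quadratic(tab, r, parameterization = "actual", space = space))
  names(models) <- responses
  anovas <- lapply(models, rsm_anova)
  pruned <- mapply(prune_model, models, anovas,
                   MoreArgs = list(alpha = config$alpha), SIMPLIFY = FALSE)

  say("[weights] source = %s", config$weights_source)
  weights <- if (config$weights_source == "computed")
    cv_weights(tab, responses)$weight
  else weight_reference()$weight

  say("[objectives] source = %s", config$objective_source)
  objectives <- switch(
    config$objective_source,
    "rsm-full" = models,
    "rsm-reduced" = pruned,
    "reference-equations" = reference_models(),
    "surrogate" = {
      nets <- lapply(seq_along(responses), function(j)
        train_surrogate(tab, responses[j], hidden = config$surrogate_hidden,
                        seed = config$seed + 7000L + j, space = space))
      names(nets) <- responses
      nets
    })

  directions <- pipeline_directions()
  bounds <- gwo_bounds(space$low, space$high)
  say("[bests] source = %s", config$best_source)
  bests <- if (config$best_source == "reference") {
    single_objective_reference()$optimum
  } else {
    vapply(seq_along(objectives), function(j) {
      obj <- as_objective_fn(objectives[j], space$names)
      f <- function(x) obj(x)[1]
      res <- if (directions[j] == "minimize")
        gwo_minimize(f, bounds, population = config$population,
                     iterations = max(50L, config$iterations %/% 5L),
                     seed = config$seed + 500L + j)
      else
        gwo_maximize(f, bounds, population = config$population,
                     iterations = max(50L, config$iterations %/% 5L),
                     seed = config$seed + 500L + j)
      res$value
    }, 0)
  }
  spec <- fitness_spec(weights = weights, directions = directions,
                       best_values = bests, indicators = responses)

  say("[mogwo] pop %d, capacity %d, %d iterations, seed %s",
      config$population, config$capacity, config$iterations,
      format(config$seed))
  archive <- mogwo(objectives, directions = directions, bounds = bounds,
                   population = config$population, capacity = config$capacity,
                   iterations = config$iterations, seed = config$seed)

  say("[pareto] averaging the %d best compromise solutions", config$k_select)
  recommendation <- pareto_select_average(
    archive, spec, k = config$k_select,
    factor_cols = space$names, response_cols = responses)

  provenance <- list(
    seed = config$seed, alpha = config$alpha,
    weights_source = config$weights_source,
    objective_source = config$objective_source,
    best_source = config$best_source,
    population = config$population, capacity = config$capacity,
    iterations = config$iterations, k_select = config$k_select,
    n_runs = nrow(tab),
    package_version = as.character(utils::packageVersion("dryopt")))

  result <- list(models = models, anovas = anovas, pruned = pruned,
                 weights = weights, spec = spec, archive = archive,
                 recommendation = recommendation, provenance = provenance,
                 config = config)
  if (!is.null(config$out_dir)) write_pipeline_reports(result, config$out_dir)
  result
}

write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  responses <- names(result$models)
  anova_tab <- do.call(rbind, lapply(responses, function(r) {
    a <- result$anovas[[r]]
    rbind(data.frame(response = r, term = "Model", df = a$model$df,
                     f = a$model$f, p = a$model$p),
          cbind(response = r, a$terms[c("term", "df", "f", "p")]),
          data.frame(response = r, term = "LackOfFit", df = a$lack_of_fit$df,
                     f = a$lack_of_fit$f, p = a$lack_of_fit$p))
  }))
  utils::write.csv(anova_tab, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(indicator = responses, weight = result$weights),
    file.path(out_dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(
    as.data.frame(result$archive,
                  factor_names = result$config$space$names,
                  objective_names = responses),
    file.path(out_dir, "pareto.csv"), row.names = FALSE)
  rec <- result$recommendation
  utils::write.csv(
    data.frame(quantity = c(names(rec$factors), names(rec$responses)),
               value = c(rec$factors, rec$responses)),
    file.path(out_dir, "recommendation.csv"), row.names = FALSE)
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate a recommended operating point against a confirmation run
#'
#' Per-indicator absolute relative error in percent with the experimental
#' value as the basis; the recommendation passes when every error is below
#' the threshold.
#'
#' @param predicted Predicted indicator vector.
#' @param experimental Measured indicator vector from the confirmation run
#'   (no zeros).
#' @param threshold Pass threshold in percent (default 5).
#' @param indicators Labels.
#' @return Object of class `validation_report` with the per-indicator
#'   errors and a `pass` flag.
#' @export
validate_recommendation <- function(predicted, experimental, threshold = 5,
                                    indicators = paste0("Y", seq_along(predicted))) {
  if (length(predicted) != length(experimental))
    stop_invalid("predicted and experimental vectors differ in length")
  if (any(experimental == 0)) stop_invalid("experimental values must be non-zero")
  errors <- vapply(seq_along(predicted), function(i)
    relative_change(experimental[i], predicted[i], basis = "reference"), 0)
  structure(list(indicators = indicators, predicted = predicted,
                 experimental = experimental, error_percent = errors,
                 threshold = threshold, pass = all(errors < threshold)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation of recommended operating point\n")
  for (i in seq_along(x$indicators))
    cat(sprintf("  %-3s predicted %8.3f  measured %8.3f  error %5.2f%%\n",
                x$indicators[i], x$predicted[i], x$experimental[i],
                x$error_percent[i]))
  cat(sprintf("=> %s (all errors %s %g%%)\n",
              if (x$pass) "PASS" else "FAIL",
              if (x$pass) "<" else "not all <", x$threshold))
  invisible(x)
}
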