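# Accessors for the reference tables shipped with the package. These are
# the published measurement and analysis tables of the 17-run Box-Behnken
# infrared combined hot-air drying experiment on yam slices that this
# pipeline re-analyzes: the full design with its six measured quality
# indicators, the per-condition thin-layer fits, the reduced regression
# equations, the single-objective optima, the indicator weights, the Pareto
# compromise set and the confirmation run.

#' The 17-run Box-Behnken drying experiment
#'
#' Design factors in actual units — drying temperature `A` (degC), slice
#' thickness `B` (mm), infrared radiation distance `C` (mm) — and the six
#' measured quality indicators: drying time `Y1` (min), CIELAB color
#' difference `Y2`, unit energy consumption `Y3` (kJ·h/kg), polysaccharide
#' content `Y4` (mg/g), rehydration ratio `Y5` (kg/kg) and allantoin
#' content `Y6` (ug/g). Twelve edge-midpoint runs plus five center
#' replicates. The source table's run-id column misprints "6" for the 16th
#' row; it is stored here as run 16.
#'
#' @return Data frame with 17 rows.
#' @export
yam_bbd_table <- function() {
  utils::read.csv(dryopt_extdata("bbd_response_table.csv"))
}

#' Tabulated thin-layer fits and diffusivities for the one-factor sweeps
#'
#' Slope and intercept of the `ln MR` versus time regressions for the
#' temperature, thickness and radiation-distance sweeps, with both the
#' published effective diffusivity (`d_eff_printed`, m^2/s) and the value
#' recomputed from the slope with the common calibration constant
#' [deff_reference_calibration] (`d_eff_recomputed`). The two published
#' anomalies are preserved as printed: the 55 degC entry (9.89e-8, where
#' slope proportionality implies 9.89e-9) and the 70 degC entry (1.79e-8,
#' which breaks proportionality). Nothing is silently corrected.
#'
#' @return Data frame with columns `sweep`, `level`, `slope`, `intercept`,
#'   `r_squared`, `d_eff_printed`, `d_eff_recomputed`.
#' @export
thin_layer_reference <- function() {
  utils::read.csv(dryopt_extdata("thin_layer_fits.csv"))
}

#' Reference reduced response-surface models
#'
#' The six significance-pruned quadratic regression equations (actual factor
#' units) as published for the drying experiment, wrapped as
#' [quadratic_model()] objects so downstream stages — truth surfaces of the
#' synthetic generator, optimizer objectives — can run bit-reproducibly from
#' fixed coefficients.
#'
#' @return Named list of six `quadratic_model` objects (`Y1`..`Y6`).
#' @export
reference_models <- function() {
  tab <- utils::read.csv(dryopt_extdata("reduced_model_coefficients.csv"))
  out <- lapply(split(tab, tab$response), function(d) {
    quadratic_model(stats::setNames(d$coefficient, d$term),
                    response = d$response[1])
  })
  out[paste0("Y", 1:6)]
}

#' Reference single-objective optima
#'
#' Best value and optimal factor settings for each indicator optimized on
#' its own over the process box. These bests anchor the composite-fitness
#' normalization.
#'
#' @return Data frame with `indicator`, `response`, `direction`, factor
#'   columns and `optimum`.
#' @export
single_objective_reference <- function() {
  utils::read.csv(dryopt_extdata("single_objective_optima.csv"))
}

#' Reference indicator-weight table
#'
#' Published coefficient-of-variation weight table (population SD, mean, CV
#' and weight per indicator, at the source's rounding). Recomputable from
#' [yam_bbd_table()] via [cv_weights()].
#'
#' @return Data frame with one row per indicator.
#' @export
weight_reference <- function() {
  utils::read.csv(dryopt_extdata("indicator_weights.csv"))
}

#' Reference Pareto compromise set
#'
#' The ten multi-objective solutions selected from the Pareto front of the
#' drying optimization, with their factor settings and predicted
#' indicators. Averaging them coordinate-wise gives the recommended
#' operating point (63.57 degC, 4.27 mm, 91.39 mm).
#'
#' @return Data frame with 10 rows.
#' @export
pareto_reference <- function() {
  utils::read.csv(dryopt_extdata("pareto_solutions.csv"))
}

#' Reference confirmation run
#'
#' Predicted indicators at the recommended operating point and the measured
#' values of the physical confirmation run performed near it.
#'
#' @return Data frame with rows `predicted` and `experimental`.
#' @export
validation_reference <- function() {
  utils::read.csv(dryopt_extdata("validation_runs.csv"))
}

#' Reference surrogate-versus-RSM fit metrics
#'
#' Published R-squared and RMSE of the quadratic response-surface fits and
#' of the grey-wolf-tuned neural surrogate, per indicator. Stochastic
#' training on 17 points makes these values non-reproducible run-for-run;
#' they are shipped for the comparative arithmetic (e.g. percent RMSE
#' reduction), not as regression targets.
#'
#' @return Data frame with `model`, `response`, `r_squared`, `rmse`.
#' @export
surrogate_fit_reference <- function() {
  utils::read.csv(dryopt_extdata("model_fit_reference.csv"))
}

#' Reference composite-fitness specification
#'
#' [fitness_spec()] built from the published indicator weights and
#' single-objective bests: weights (0.18, 0.25, 0.16, 0.15, 0.12, 0.13),
#' bests (136.37, 3.3, 6.75, 26.23, 2.97, 3.81), minimizing the first three
#' indicators and maximizing the last three.
#'
#' @return A `fitness_spec`.
#' @export
reference_fitness_spec <- function() {
  w <- weight_reference()
  s <- single_objective_reference()
  fitness_spec(weights = w$weight, directions = s$direction,
               best_values = s$optimum, indicators = w$response)
}
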