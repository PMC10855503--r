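# Synthetic data with the statistical structure the analysis assumes:
# exponential thin-layer drying curves anchored to the tabulated log-linear
# slopes, and Box-Behnken response tables generated from the reference
# quadratic surfaces with Gaussian noise calibrated to the tabulated model
# C.V.%. Every pipeline stage can therefore be exercised end to end without
# any measured input.

#' Specification of the synthetic-data generator
#'
#' The defaults ARE the study conditions of the reference experiment:
#' truth surfaces from [reference_models()], per-response noise
#' `sigma = CV% * mean / 100` with the tabulated model C.V.% values, the
#' tabulated thin-layer slope anchors, initial moisture 5.362 g/g dry basis
#' (84.28% wet basis), a 15-min weighing cadence, a 150 g sample load and a
#' 0.13 kg/kg (wet basis) target moisture.
#'
#' @param models Named list of truth surfaces (`quadratic_model`s), `Y1`..`Y6`.
#' @param cv_percent Per-response noise level as a percent of the mean
#'   truth response over the design.
#' @param anchors Thin-layer slope anchor table (see
#'   [thin_layer_reference()]).
#' @param m0 Initial dry-basis moisture, g/g.
#' @param interval_min Weighing cadence, minutes.
#' @param target_wet_basis Stop criterion: wet-basis moisture fraction.
#' @param load_g Nominal fresh sample load, grams.
#' @param mass_noise_sd Multiplicative Gaussian noise SD on weighings.
#' @param space The [factor_space()].
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(models = reference_models(),
                           cv_percent = c(5.5, 3.56, 4.83, 5.71, 1.87, 2.01),
                           anchors = thin_layer_reference(),
                           m0 = 5.362, interval_min = 15,
                           target_wet_basis = 0.13, load_g = 150,
                           mass_noise_sd = 0.002, space = factor_space()) {
  if (any(cv_percent < 0)) stop_invalid("noise levels must be >= 0")
  check_number(interval_min, "interval_min", positive = TRUE)
  check_number(m0, "m0", positive = TRUE)
  structure(list(models = models, cv_percent = cv_percent, anchors = anchors,
                 m0 = m0, interval_min = interval_min,
                 target_wet_basis = target_wet_basis, load_g = load_g,
                 mass_noise_sd = mass_noise_sd, space = space),
            class = "generator_spec")
}

# Thin-layer decay constant (per weighing interval) at arbitrary factor
# settings: log-linear interpolation along each one-factor sweep relative to
# the shared center condition (60 degC, 6 mm, 120 mm). The anchor tables are
# per-axis sweeps, so the cross-factor surface is a separable modeling
# convenience, not a measured fact.
interpolate_slope <- function(anchors, temperature, thickness, distance) {
  axis_log_k <- function(sweep, at) {
    d <- anchors[anchors$sweep == sweep, ]
    stats::approx(d$level, log(d$slope), xout = at, rule = 2)$y
  }
  k0 <- log(anchors$slope[anchors$sweep == "temperature" &
                            anchors$level == 60][1])
  exp(axis_log_k("temperature", temperature) +
        axis_log_k("thickness", thickness) +
        axis_log_k("distance", distance) - 2 * k0)
}

#' Simulate one thin-layer drying curve
#'
#' Generates `MR(t) = exp(-k t)` with the decay constant interpolated from
#' the tabulated one-factor slope anchors (slopes are treated as per
#' 15-min weighing interval), back-computes total masses from the initial
#' moisture and sample load, applies multiplicative Gaussian weighing noise
#' (the first weighing is kept exact), and truncates once the target
#' moisture is reached.
#'
#' @param temperature,thickness,distance Process settings (within the box).
#' @param spec A [generator_spec()].
#' @param noise Apply weighing noise? (`FALSE` gives the exact exponential.)
#' @param seed Integer seed.
#' @param max_minutes Safety cap on run duration; hitting it warns.
#' @return A [drying_curve()].
#' @export
simulate_drying_curve <- function(temperature = 60, thickness = 6,
                                  distance = 120, spec = generator_spec(),
                                  noise = TRUE, seed = NULL,
                                  max_minutes = 1440) {
  stopifnot(inherits(spec, "generator_spec"))
  k_interval <- interpolate_slope(spec$anchors, temperature, thickness, distance)
  k_min <- k_interval / spec$interval_min
  m_target <- wet_to_dry_basis(spec$target_wet_basis)
  mr_target <- m_target / spec$m0
  t_end <- -log(mr_target) / k_min
  if (t_end > max_minutes) {
    warning("target moisture not reached within `max_minutes`; truncating")
    t_end <- max_minutes
  }
  times <- seq(0, ceiling(t_end / spec$interval_min) * spec$interval_min,
               by = spec$interval_min)
  mr <- exp(-k_min * times)
  dry_mass <- spec$load_g / (1 + spec$m0)
  masses <- dry_mass * (1 + spec$m0 * mr)
  if (noise && spec$mass_noise_sd > 0) {
    masses <- with_seed(seed, {
      eps <- c(0, stats::rnorm(length(masses) - 1, 0, spec$mass_noise_sd))
      pmax(masses * (1 + eps), dry_mass * (1 + 1e-9))
    })
  }
  drying_curve(times, masses, dry_mass, temperature = temperature,
               thickness_mm = thickness, distance_mm = distance)
}

#' Simulate a Box-Behnken response table
#'
#' Evaluates the truth surfaces at every design point and adds independent
#' Gaussian noise with `sigma_j = cv_percent_j * mean(truth_j) / 100`;
#' center replicates get independent draws.
#'
#' @param design Design skeleton from [bbd_design()].
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return Data frame shaped like [yam_bbd_table()].
#' @export
simulate_bbd_table <- function(design = bbd_design(), spec = generator_spec(),
                               seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  responses <- names(spec$models)
  out <- design[c("run", spec$space$names)]
  with_seed(seed, {
    for (j in seq_along(responses)) {
      truth <- stats::predict(spec$models[[j]], design,
                              extrapolation_warning = FALSE)
      sigma <- spec$cv_percent[j] / 100 * mean(truth)
      out[[responses[j]]] <- truth + stats::rnorm(length(truth), 0, sigma)
    }
    out
  })
}

#' Parameter-recovery experiment over the full pipeline
#'
#' Per replicate: simulate a Box-Behnken table from the truth surfaces,
#' run the complete analysis (quadratic fits, pruning, CV weights,
#' multi-objective grey wolf search, Pareto-set averaging) and record the
#' recommended operating point. Reports the spread of the recommendations
#' around the deterministic truth-surface recommendation, i.e. how much the
#' calibrated measurement noise moves the final answer.
#'
#' @param spec A [generator_spec()].
#' @param n_replicates Number of simulated experiments.
#' @param seed Integer base seed (each replicate derives its own).
#' @param population,iterations,capacity,k_select Optimizer settings for
#'   the per-replicate search (scaled-down defaults keep a replicate cheap).
#' @return List with per-replicate recommendations, the truth-surface
#'   recommendation and bias/spread summaries per factor.
#' @export
recovery_experiment <- function(spec = generator_spec(), n_replicates = 3,
                                seed = 1, population = 40, iterations = 60,
                                capacity = 50, k_select = 10) {
  if (n_replicates < 1) stop_invalid("need at least one replicate")
  run_one <- function(table, rep_seed) {
    cfg <- pipeline_config(table = table, objective_source = "rsm-reduced",
                           population = population, iterations = iterations,
                           capacity = capacity, k_select = k_select,
                           seed = rep_seed)
    run_pipeline(cfg, quiet = TRUE)$recommendation
  }
  truth_table <- simulate_bbd_table(
    spec = generator_spec(models = spec$models,
                          cv_percent = rep(0, length(spec$cv_percent)),
                          anchors = spec$anchors), seed = seed)
  truth_rec <- run_one(truth_table, rep_seed = seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    tab <- simulate_bbd_table(spec = spec, seed = seed + 100L * r)
    run_one(tab, rep_seed = seed + 100L * r)
  })
  factors <- do.call(rbind, lapply(reps, function(x) x$factors))
  list(replicates = reps,
       truth_recommendation = truth_rec,
       factor_recommendations = as.data.frame(factors),
       bias = colMeans(factors) - truth_rec$factors,
       spread = apply(factors, 2, stats::sd))
}
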