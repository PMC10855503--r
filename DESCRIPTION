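Package: dryopt
Title: Multi-Objective Optimization of Thin-Layer Drying Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for infrared combined hot-air drying experiments
    on sliced plant material. Computes thin-layer drying kinetics (moisture
    ratio, drying rate, effective moisture diffusivity), quality indices
    (CIELAB color difference, rehydration ratio, unit energy consumption,
    standard-curve concentrations), fits Box-Behnken quadratic response-surface
    models with full ANOVA and significance pruning, derives
    coefficient-of-variation indicator weights and a composite scalarized
    fitness, trains small feed-forward neural surrogates by backpropagation,
    and searches the process box with single- and multi-objective Grey Wolf
    Optimizers (external Pareto archive with hypercube-grid crowding).
    Includes a synthetic-data generator emulating exponential drying curves
    and noisy quadratic response surfaces for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
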