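#' CIELAB color difference
#'
#' Euclidean distance between two (L, a, b) triples — total color change of
#' the dried product relative to the fresh reference.
#'
#' @param fresh,dried Numeric length-3 vectors `(L, a, b)`.
#' @return Delta E, dimensionless and non-negative.
#' @export
color_difference <- function(fresh, dried) {
  check_number(fresh, "fresh"); check_number(dried, "dried")
  if (length(fresh) != 3 || length(dried) != 3)
    stop_invalid("color triples must have length 3 (L, a, b)")
  sqrt(sum((fresh - dried)^2))
}

#' Rehydration ratio
#'
#' Mass of the sample after soaking divided by its mass before soaking; a
#' proxy for how much the cellular structure survived drying.
#'
#' @param mass_after Mass after rehydration, g.
#' @param mass_before Mass before rehydration, g (> 0).
#' @return Ratio in kg/kg. Values below 1 are physically odd (the sample lost
#'   mass while soaking) and trigger a warning but are returned.
#' @export
rehydration_ratio <- function(mass_after, mass_before) {
  check_number(mass_after, "mass_after")
  check_number(mass_before, "mass_before", positive = TRUE)
  r <- mass_after / mass_before
  if (any(r < 1)) warning("rehydration ratio below 1: sample lost mass while soaking")
  r
}

#' Unit energy consumption
#'
#' Metered energy divided by the mass of water removed during the run. The
#' unit kJ·h/kg follows the source instrumentation's convention and is kept
#' as reported.
#'
#' @param total_energy Metered energy over the run, kJ·h.
#' @param water_removed Mass of water removed, kg (> 0).
#' @return Unit energy consumption, kJ·h/kg.
#' @export
unit_energy <- function(total_energy, water_removed) {
  check_number(total_energy, "total_energy")
  check_number(water_removed, "water_removed", positive = TRUE)
  total_energy / water_removed
}

#' Spectrophotometric standard curve
#'
#' Affine absorbance-versus-concentration calibration `y = slope * x +
#' intercept`. The default is the glucose calibration used for the
#' phenol-sulfuric polysaccharide assay (absorbance at 490 nm against mg/mL
#' glucose).
#'
#' @param slope Absorbance per unit concentration; non-zero.
#' @param intercept Absorbance at zero concentration.
#' @param r_squared Calibration fit quality (bookkeeping only).
#' @return Object of class `standard_curve`.
#' @export
standard_curve <- function(slope = 11.8557, intercept = -0.0206,
                           r_squared = 0.9564) {
  check_number(slope, "slope")
  if (slope == 0) stop_invalid("standard curve slope must be non-zero")
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared),
            class = "standard_curve")
}

#' Concentration from absorbance
#'
#' Inverts the affine standard curve: `x = (y - intercept) / slope`.
#' Negative concentrations (absorbance below the blank) are returned with a
#' warning rather than clipped, so assay problems stay visible.
#'
#' @param absorbance Measured absorbance (vectorized).
#' @param curve A [standard_curve()].
#' @return Concentration in the curve's units.
#' @export
concentration_from_absorbance <- function(absorbance, curve = standard_curve()) {
  stopifnot(inherits(curve, "standard_curve"))
  check_number(absorbance, "absorbance")
  x <- (absorbance - curve$intercept) / curve$slope
  if (any(x < 0)) warning("negative concentration: absorbance below the blank")
  x
}

#' Relative change between two values, in percent
#'
#' `100 * |value - reference| / basis`. Which of the two values (or the
#' larger one) serves as the denominator is an explicit argument because
#' percentage conventions differ between contexts — e.g. "time increased by
#' 62.5%" computed against the larger value versus a prediction error
#' computed against the experimental reference — and silently guessing the
#' basis invites misreadings.
#'
#' @param reference Reference value.
#' @param value Compared value.
#' @param basis One of `"reference"`, `"value"`, `"larger"`; the denominator.
#' @return Absolute relative change in percent.
#' @export
relative_change <- function(reference, value,
                            basis = c("reference", "value", "larger")) {
  basis <- match.arg(basis)
  check_number(reference, "reference"); check_number(value, "value")
  denom <- switch(basis,
                  reference = reference,
                  value = value,
                  larger = pmax(abs(reference), abs(value)))
  if (any(denom == 0)) stop_invalid("chosen basis is zero")
  100 * abs(value - reference) / abs(denom)
}
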