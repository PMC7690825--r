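#' Calorimetric constants
#'
#' Bundle of the fixed coefficients used throughout the energy ledger: the
#' Brouwer heat-production coefficients, the energetic value of methane, the
#' nitrogen-to-protein conversion, the energy content of body protein, the
#' metabolic bodyweight exponent, the reference metabolizable-energy intake
#' used when adjusting heat production to a common feeding level, and the
#' lower-critical-temperature regression for growing pigs.
#'
#' All values are the standard livestock-calorimetry constants; any of them
#' can be overridden for sensitivity analyses.
#'
#' @param ... named overrides of the default constants.
#'
#' @return A list of class `calorimetry_constants` with elements
#'   `brouwer_o2`, `brouwer_co2`, `brouwer_ch4`, `brouwer_n` (kJ per L gas or
#'   per g urinary N), `methane_energy_kJ_per_L`, `n_to_protein`,
#'   `protein_energy_kJ_per_g`, `metabolic_exponent`,
#'   `reference_mei_kJ_per_kgMBW`, `lct_intercept_C`, `lct_slope_C_per_kg`.
#'
#' @examples
#' k <- calorimetry_constants()
#' k$brouwer_o2
#' calorimetry_constants(metabolic_exponent = 0.75)$metabolic_exponent
#' @export
calorimetry_constants <- function(...) {
  k <- list(
    brouwer_o2  = 16.18,
    brouwer_co2 = 5.02,
    brouwer_ch4 = 2.17,
    brouwer_n   = 5.99,
    methane_energy_kJ_per_L = 39.4,
    n_to_protein = 6.25,
    protein_energy_kJ_per_g = 23.86,
    metabolic_exponent = 0.6,
    reference_mei_kJ_per_kgMBW = 2400,
    lct_intercept_C = 17.9,
    lct_slope_C_per_kg = 0.0375
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(k))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    k[names(dots)] <- dots
  }
  stopifnot(all(vapply(k, function(x) is.numeric(x) && x > 0, logical(1))))
  class(k) <- "calorimetry_constants"
  k
}

#' Metabolic bodyweight
#'
#' Bodyweight raised to the metabolic scaling exponent (0.6 for growing
#' pigs), the basis on which all energy-balance rates are expressed.
#'
#' @param bw_kg bodyweight in kg (vectorised, must be positive).
#' @param exponent scaling exponent; default 0.6.
#' @return `bw_kg ^ exponent`, in kg^exponent.
#' @examples
#' metabolic_bw(28.7)
#' @export
metabolic_bw <- function(bw_kg, exponent = 0.6) {
  if (any(!is.finite(bw_kg)) || any(bw_kg <= 0))
    stop("bodyweight must be positive and finite")
  bw_kg^exponent
}

#' Lower critical temperature of growing pigs
#'
#' Linear decline of the lower critical temperature (the cold boundary of the
#' thermoneutral zone) with bodyweight: `LCT = 17.9 - 0.0375 * BW`.
#'
#' @param bw_kg bodyweight in kg (vectorised, nonnegative).
#' @param constants a [calorimetry_constants()] bundle.
#' @return LCT in degrees Celsius.
#' @examples
#' lct(26.4)
#' lct(64.2)
#' @export
lct <- function(bw_kg, constants = calorimetry_constants()) {
  if (any(!is.finite(bw_kg)) || any(bw_kg < 0))
    stop("bodyweight must be nonnegative and finite")
  constants$lct_intercept_C - constants$lct_slope_C_per_kg * bw_kg
}
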