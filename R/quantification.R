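#' Pigment concentrations from a methanol-extract absorbance panel
#'
#' Spectrophotometric chlorophyll and carotenoid quantification for methanol
#' extracts. Each absorbance is first turbidity-corrected by subtracting the
#' 750 nm reading, then
#' \deqn{chl_a = (V_e / V_b) (-8.0962 A_{652} + 16.5169 A_{665})}
#' \deqn{chl_b = (V_e / V_b) (27.4405 A_{652} - 12.1688 A_{665})}
#' \deqn{car   = (V_e / V_b) \cdot 4 A_{480}}
#' with extract volume \eqn{V_e} (1.5 mL methanol by default) and biomass
#' sample volume \eqn{V_b}; concentrations in ug/mL. Absorbance ratios
#' outside the formulas' calibration domain can produce negative values;
#' these are returned with a warning rather than clipped.
#'
#' @param A480,A652,A665 Raw absorbances (dimensionless).
#' @param A750 Turbidity absorbance subtracted from each channel (default 0).
#' @param V_biomass Biomass sample volume (mL), > 0.
#' @param extract_volume Solvent volume (mL), default 1.5.
#' @return data.frame with columns chl_a, chl_b, carotenoids (ug/mL) and
#'   logical `domain_warning`.
#' @export
pigment_concentrations <- function(A480, A652, A665, A750 = 0,
                                   V_biomass = 1.5, extract_volume = 1.5) {
  if (any(V_biomass <= 0)) stop("V_biomass must be positive", call. = FALSE)
  a480 <- A480 - A750
  a652 <- A652 - A750
  a665 <- A665 - A750
  f <- extract_volume / V_biomass
  chl_a <- f * (-8.0962 * a652 + 16.5169 * a665)
  chl_b <- f * (27.4405 * a652 - 12.1688 * a665)
  car <- f * 4 * a480
  neg <- chl_a < 0 | chl_b < 0 | car < 0
  if (any(neg))
    warning("negative pigment concentration(s): absorbance ratios outside the formulas' domain",
            call. = FALSE)
  data.frame(chl_a = chl_a, chl_b = chl_b, carotenoids = car,
             domain_warning = neg)
}

#' Total lipid concentration from gravimetry
#'
#' Mass of the dried lipid extract divided by the culture sample volume.
#'
#' @param extract_mass_mg Extract mass (mg), > 0.
#' @param sample_volume_L Sample volume (L), > 0.
#' @return Concentration in mg/L.
#' @export
total_lipid_concentration <- function(extract_mass_mg, sample_volume_L) {
  if (any(extract_mass_mg <= 0) || any(sample_volume_L <= 0))
    stop("extract mass and sample volume must be positive", call. = FALSE)
  extract_mass_mg / sample_volume_L
}

#' Dilution-corrected optical density
#'
#' Cultures are diluted until the measured OD falls below 0.8 (the linear
#' range of the spectrophotometer); the true density is the measured value
#' times the dilution factor. A measured OD at or above 0.8 is returned with
#' a validity flag rather than rejected.
#'
#' @param od_measured Measured absorbance of the (diluted) sample.
#' @param dilution_factor Dilution factor, >= 1.
#' @return data.frame with columns od (corrected) and `out_of_range` flag.
#' @export
corrected_od <- function(od_measured, dilution_factor = 1) {
  if (any(dilution_factor < 1))
    stop("dilution_factor must be >= 1", call. = FALSE)
  data.frame(od = od_measured * dilution_factor,
             out_of_range = od_measured >= 0.8)
}
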