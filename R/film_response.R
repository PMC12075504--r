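## Radiochromic-film response corrections: LET quenching efficiency and
## spectrum-weighted quenching correction factor (QCF), dose-to-water
## equivalence (DWE), and the calibration-energy correction.

#' LET quenching efficiency of radiochromic film
#'
#' Linear under-response model `eta = -0.0251 * LET[keV/um] + 1.02`,
#' clamped below at 0.05 where the linear law would go non-positive
#' (end-of-range bins; the clamp avoids division blow-up and affects only
#' negligible-dose bins).
#'
#' @param let LET in keV/um (>= 0, vectorized).
#' @return dimensionless efficiency.
#' @export
eta_let <- function(let) {
  if (any(let < 0)) stop("LET must be >= 0")
  pmax(-0.0251 * let + 1.02, 0.05)
}

#' Quenching correction factor of a proton spectrum
#'
#' Dose-weighted mean of the reciprocal quenching efficiency:
#' `QCF = sum_i D_i N_i / eta(E_i) / sum_i D_i N_i`, with `eta` evaluated
#' at the LET of the film's active-layer material at the bin energy at
#' the plane.  For any physical proton spectrum QCF >= 1/1.02.
#'
#' @param spectrum data.frame with columns `E_mid` (MeV), `N` (fluence
#'   counts) and `D` (per-primary dose contribution, Gy).
#' @param active_material the film's sensitive-layer material (default
#'   the EBT-XD active layer).
#' @return dimensionless correction factor.
#' @export
qcf <- function(spectrum, active_material = "ebtxd_active") {
  w <- spectrum$D * spectrum$N
  if (!any(w > 0)) stop("spectrum carries no deposited dose")
  sel <- w > 0
  let <- let_in_material(active_material, spectrum$E_mid[sel])
  sum(w[sel] / eta_let(let)) / sum(w[sel])
}

#' Dose-to-water equivalence factor of a proton spectrum
#'
#' Fluence-weighted mean of the mass-stopping-power ratio between water
#' and the film reference material:
#' `DWE = sum_i N_i S_water(E_i) / S_film(E_i) / sum_i N_i`.
#'
#' @param spectrum data.frame with columns `E_mid` and `N`.
#' @param film_material reference material of the film calibration
#'   (default mylar).
#' @return dimensionless factor.
#' @export
dwe <- function(spectrum, film_material = "mylar") {
  if (!any(spectrum$N > 0)) stop("empty spectrum")
  sel <- spectrum$N > 0
  e <- spectrum$E_mid[sel]
  sw <- as.numeric(mass_stopping_power("water", e, warn_clamp = FALSE))
  sf <- as.numeric(mass_stopping_power(film_material, e, warn_clamp = FALSE))
  sum(spectrum$N[sel] * sw / sf) / sum(spectrum$N[sel])
}

#' Correction set for one film plane
#'
#' @param QCF quenching correction factor (>= 1/1.02 for proton spectra).
#' @param DWE dose-to-water equivalence factor (in (0.5, 1.5)).
#' @param calibration_factor multiplicative correction for film quenching
#'   at the water-calibration energy; default `1 - 0.065` (the film
#'   calibration overestimates dose by 6.5%).
#' @return an object of class `correction_set`.
#' @export
correction_set <- function(QCF = 1, DWE = 1,
                           calibration_factor = 1 - 0.065) {
  if (DWE <= 0.5 || DWE >= 1.5) stop("DWE outside (0.5, 1.5)")
  structure(list(QCF = QCF, DWE = DWE,
                 calibration_factor = calibration_factor),
            class = "correction_set")
}

#' Apply quenching and calibration corrections to a measured film dose
#'
#' `corrected = measured * QCF * calibration_factor`.
#'
#' @param measured measured film dose in Gy (>= 0, vectorized).
#' @param corrections a [correction_set].
#' @return corrected dose in Gy.
#' @export
correct_measured_dose <- function(measured, corrections) {
  if (any(measured < 0)) stop("measured dose must be >= 0")
  measured * corrections$QCF * corrections$calibration_factor
}
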