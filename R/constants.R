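#' Physical and unit-conversion constants
#'
#' A single place for the fixed conversion factors used throughout the model:
#' the atmospheric CO2 mass-to-mixing-ratio factor, the carbon/CO2 mass ratio,
#' the CO2 molar mass, mean seawater density, and reference preindustrial
#' greenhouse-gas abundances. Stated once so every module shares the same
#' values.
#'
#' @format A named list:
#' \describe{
#'   \item{gtc_per_ppm}{GtC in the atmosphere per ppm CO2 (2.124).}
#'   \item{gtco2_per_gtc}{Mass ratio CO2:C (44.01/12.011).}
#'   \item{co2_molar_mass}{g per mol CO2 (44.01).}
#'   \item{rho_sw}{Mean seawater density, kg m-3.}
#'   \item{ocean_area}{Global ocean surface area, m2.}
#'   \item{ocean_volume}{Global ocean volume, m3.}
#'   \item{co2_ppm_pi, ch4_ppb_pi, n2o_ppb_pi}{Preindustrial abundances.}
#'   \item{sv_m3yr}{m3 per year in one Sverdrup.}
#' }
#' @export
erw_constants <- list(
  gtc_per_ppm    = 2.124,
  gtco2_per_gtc  = 44.01 / 12.011,
  co2_molar_mass = 44.01,
  c_molar_mass   = 12.011,
  rho_sw         = 1026.5,
  ocean_area     = 3.62e14,
  ocean_volume   = 1.33e18,
  co2_ppm_pi     = 278,
  ch4_ppb_pi     = 722,
  n2o_ppb_pi     = 270,
  sv_m3yr        = 1e6 * 3.15576e7
)

# GtCO2 -> mol CO2
gtco2_to_mol <- function(x) x * 1e15 / erw_constants$co2_molar_mass

# mol C -> GtC
mol_to_gtc <- function(x) x * erw_constants$c_molar_mass / 1e15

gtc_to_mol <- function(x) x * 1e15 / erw_constants$c_molar_mass

gtc_to_gtco2 <- function(x) x * erw_constants$gtco2_per_gtc

gtco2_to_gtc <- function(x) x / erw_constants$gtco2_per_gtc
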