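#' Unit conversions between field and internal (cm-g-year) units
#'
#' The model works internally in cm, g and years.  Field quantities are
#' usually reported per hectare, per day or in t/ha; these helpers perform
#' the documented conversions (1 ha = 1e8 cm^2, 1 t = 1e6 g, 1 kg = 1e3 g,
#' 1 year = 365 days, 1 g/cm^3 = 1e6 g/m^3).
#'
#' `areal_to_volumetric()` spreads an areal mass density (kg/ha) over a layer
#' of given thickness, e.g. an earthworm biomass of 655 kg/ha over 0-30 cm is
#' 2.183e-4 g/cm^3 (218 g/m^3).  `root_input_rate()` converts an above-ground
#' production (t/ha/yr) with a below-ground fraction into a root biomass
#' input rate per unit soil volume (g cm^-3 yr^-1), e.g. 30% of 10 t/ha/yr
#' into a 25 cm layer is 0.0012 g cm^-3 yr^-1.
#'
#' @param kg_ha Areal density, kg/ha.
#' @param depth_cm Layer thickness, cm.
#' @return `areal_to_volumetric()`: g/cm^3.
#' @export
areal_to_volumetric <- function(kg_ha, depth_cm) {
  if (any(depth_cm <= 0)) stop("`depth_cm` must be positive", call. = FALSE)
  kg_ha * 1e3 / (1e8 * depth_cm)
}

#' @rdname areal_to_volumetric
#' @param x Concentration in g/cm^3.
#' @return `g_cm3_to_g_m3()`: g/m^3.
#' @export
g_cm3_to_g_m3 <- function(x) x * 1e6

#' @rdname areal_to_volumetric
#' @param above_t_ha_yr Above-ground biomass production, t ha^-1 yr^-1.
#' @param fraction Below-ground (root) fraction of that production.
#' @return `root_input_rate()`: g cm^-3 yr^-1.
#' @export
root_input_rate <- function(above_t_ha_yr, fraction, depth_cm) {
  if (any(depth_cm <= 0)) stop("`depth_cm` must be positive", call. = FALSE)
  fraction * above_t_ha_yr * 1e6 / (1e8 * depth_cm)
}

#' @rdname areal_to_volumetric
#' @param rate_per_day A rate expressed per day.
#' @return `per_day_to_per_year()`: the same rate per year (365 days/yr).
#' @export
per_day_to_per_year <- function(rate_per_day) rate_per_day * 365
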