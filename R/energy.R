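#' Emission accounting settings
#'
#' Emission factors for a fossil-fuel combined-cycle power plant
#' (CO2: 622 g/kWh, NOx: 3.78 g/kWh), an optional emission-reduction
#' percentage ER, and the plant/transmission efficiency dividing metered
#' energy into primary ("real") energy.
#'
#' @param ef_co2_g_per_kWh CO2 emission factor (g/kWh).
#' @param ef_nox_g_per_kWh NOx emission factor (g/kWh).
#' @param er_pct Emission-reduction percentage ER in `[0, 100]`.
#' @param plant_efficiency Plant/transmission efficiency in (0, 1].
#' @return Object of class `rw_emission_settings`.
#' @export
emission_settings <- function(ef_co2_g_per_kWh = 622,
                              ef_nox_g_per_kWh = 3.78,
                              er_pct = 0, plant_efficiency = 0.871) {
  if (ef_co2_g_per_kWh <= 0 || ef_nox_g_per_kWh <= 0)
    stopf("emission factors must be > 0")
  if (er_pct < 0 || er_pct > 100) stopf("er_pct must be in [0, 100]")
  if (plant_efficiency <= 0 || plant_efficiency > 1)
    stopf("plant_efficiency must be in (0, 1]")
  structure(list(ef_co2_g_per_kWh = ef_co2_g_per_kWh,
                 ef_nox_g_per_kWh = ef_nox_g_per_kWh,
                 er_pct = er_pct, plant_efficiency = plant_efficiency),
            class = "rw_emission_settings")
}

#' Water removed during drying (wet-basis mass balance)
#'
#' `m_w = m0 (M0 - Mf) / (100 - Mf)`: the dry matter `m0 (1 - M0/100)`
#' is conserved, so the final mass is dry matter over `1 - Mf/100`.
#'
#' @param initial_mass_kg Initial wet mass (kg).
#' @param M0_wb_pct Initial wet-basis moisture (%).
#' @param Mf_wb_pct Final wet-basis moisture (%), below `M0_wb_pct`.
#' @return Mass of water removed (kg).
#' @export
water_removed <- function(initial_mass_kg, M0_wb_pct, Mf_wb_pct) {
  if (any(Mf_wb_pct < 0) || any(M0_wb_pct >= 100))
    stopf("moistures must satisfy 0 <= Mf < M0 < 100")
  if (any(Mf_wb_pct > M0_wb_pct))
    stopf("final moisture must not exceed initial moisture")
  initial_mass_kg * (M0_wb_pct - Mf_wb_pct) / (100 - Mf_wb_pct)
}

#' Specific energy consumption
#'
#' Metered electrical energy per kilogram of water removed.
#'
#' @param total_kWh Total energy supplied during drying (kWh).
#' @param water_removed_kg Water removed (kg), positive.
#' @return SEC in kWh/kg water.
#' @export
specific_energy <- function(total_kWh, water_removed_kg) {
  if (any(water_removed_kg <= 0)) stopf("water_removed_kg must be > 0")
  total_kWh / water_removed_kg
}

#' Pollutant emission intensity of drying
#'
#' `SEC_real = SEC / plant_efficiency`; intensity =
#' `SEC_real * EF * (1 - ER/100)` with the emission factor converted from
#' g/kWh to kg/kWh.  Result is kilograms of pollutant per kilogram of
#' water removed.
#'
#' @param sec_kWh_per_kg Specific energy consumption (kWh/kg water).
#' @param settings An [emission_settings()] object.
#' @param pollutant `"co2"` or `"nox"`.
#' @return Emission intensity (kg pollutant / kg water).
#' @export
emission_intensity <- function(sec_kWh_per_kg,
                               settings = emission_settings(),
                               pollutant = c("co2", "nox")) {
  stopifnot(inherits(settings, "rw_emission_settings"))
  pollutant <- match.arg(pollutant)
  ef <- switch(pollutant, co2 = settings$ef_co2_g_per_kWh,
               nox = settings$ef_nox_g_per_kWh)
  sec_real <- sec_kWh_per_kg / settings$plant_efficiency
  sec_real * (ef / 1000) * (1 - settings$er_pct / 100)
}

#' Percent change relative to a reference value
#'
#' `100 (reference - new) / reference`; positive values are decreases.
#'
#' @param reference_value Reference (nonzero).
#' @param new_value New value.
#' @return Percent change.
#' @export
percent_change <- function(reference_value, new_value) {
  if (any(reference_value == 0)) stopf("reference value must be nonzero")
  100 * (reference_value - new_value) / reference_value
}

#' Full energy/emission record for one drying condition
#'
#' @param temperature_C Temperature label (degrees C).
#' @param total_kWh Metered energy (kWh).
#' @param water_removed_kg Water removed (kg).
#' @param settings An [emission_settings()] object.
#' @return One-row data.frame with SEC, SEC_real, CO2 and NOx
#'   intensities.
#' @export
energy_record <- function(temperature_C, total_kWh, water_removed_kg,
                          settings = emission_settings()) {
  sec <- specific_energy(total_kWh, water_removed_kg)
  data.frame(
    temperature_C = temperature_C, total_kWh = total_kWh,
    water_removed_kg = water_removed_kg,
    sec_kWh_per_kg = sec,
    sec_real_kWh_per_kg = sec / settings$plant_efficiency,
    co2_kg_per_kg = emission_intensity(sec, settings, "co2"),
    nox_kg_per_kg = emission_intensity(sec, settings, "nox")
  )
}
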