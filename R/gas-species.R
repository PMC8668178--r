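#' Gas species constants
#'
#' Reference table of the five monitored gases with the molecular weights and
#' concentration-unit conventions used throughout the flux calculations.
#' NH3 and H2S concentrations are carried in micrograms per litre (so the
#' gram-standardizing denominator is 1e9); CH4, CO2 and N2O are carried in
#' milligrams per litre (denominator 1e6).
#'
#' @return A tibble with columns `gas`, `mw` (g/mol), `unit` and
#'   `denominator`.
#' @export
#' @examples
#' gas_species()
gas_species <- function() {
  tibble::tibble(
    gas = c("NH3", "CH4", "CO2", "H2S", "N2O"),
    mw = c(17.03, 16.04, 44.01, 34.08, 44.01),
    unit = c("ug/L", "mg/L", "mg/L", "ug/L", "mg/L"),
    denominator = c(1e9, 1e6, 1e6, 1e9, 1e6)
  )
}

#' Physical constants for the flux conversion
#'
#' Molar volume at the analyzers' controlled temperature and pressure
#' (22.4 L/mol), litres per cubic metre, and the Celsius-to-kelvin offset.
#'
#' @return Named list with `vs_l_mol`, `litres_per_m3`, `kelvin_offset`.
#' @export
flux_constants <- function() {
  list(vs_l_mol = 22.4, litres_per_m3 = 1000, kelvin_offset = 273.15)
}

# Look up species rows, stopping on unknown gases.
species_info <- function(gas) {
  sp <- gas_species()
  idx <- match(gas, sp$gas)
  if (anyNA(idx)) {
    rlang::abort(paste0(
      "unknown gas species: ",
      paste(unique(gas[is.na(idx)]), collapse = ", ")
    ))
  }
  sp[idx, ]
}
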