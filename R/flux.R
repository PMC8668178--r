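#' Total enclosure airflow at a point in time
#'
#' Each ventilation fan is calibrated twice per cycle (flow at the start and
#' at the end); fan output decays approximately linearly between the two
#' calibrations, so the flow of a fan at time `t` is the linear interpolation
#' between its two calibrated rates, and enclosure outflow is the sum over
#' its fans. No extrapolation outside the calibration window is permitted.
#'
#' @param fans Data frame of fan calibrations with columns `fan_id`,
#'   `t0`, `t1` (seconds), `flow_start`, `flow_end` (m^3/min). All rows must
#'   belong to a single enclosure (and cycle).
#' @param t Numeric vector of query times (seconds, same clock as `t0`/`t1`).
#' @return Numeric vector of total airflow (m^3/min), one value per `t`.
#' @export
#' @examples
#' fans <- tibble::tibble(
#'   fan_id = c("a", "b"), t0 = 0, t1 = 100,
#'   flow_start = c(60, 60), flow_end = c(40, 40)
#' )
#' airflow_at(fans, 50) # 100
airflow_at <- function(fans, t) {
  stopifnot(all(c("t0", "t1", "flow_start", "flow_end") %in% names(fans)))
  if (any(fans$flow_start <= 0) || any(fans$flow_end <= 0)) {
    rlang::abort("fan calibration flows must be strictly positive")
  }
  if (any(fans$t1 <= fans$t0)) {
    rlang::abort("fan calibration requires t1 > t0")
  }
  if (any(t < max(fans$t0) - 1e-9) || any(t > min(fans$t1) + 1e-9)) {
    rlang::abort("query time outside the fan calibration window; no extrapolation")
  }
  total <- numeric(length(t))
  for (i in seq_len(nrow(fans))) {
    frac <- (t - fans$t0[i]) / (fans$t1[i] - fans$t0[i])
    total <- total + fans$flow_start[i] + frac * (fans$flow_end[i] - fans$flow_start[i])
  }
  total
}

#' Net gas concentration
#'
#' Enclosure concentration minus the concurrent ambient (incoming)
#' concentration, in the species' native unit. Negative values are real
#' (an enclosure can run below ambient, as routinely happens for N2O) and
#' are never clamped.
#'
#' @param cpe_value,ambient_value Numeric vectors, same unit and species.
#' @param unit,ambient_unit Optional unit labels; if both are given they must
#'   match.
#' @return `cpe_value - ambient_value`.
#' @export
net_concentration <- function(cpe_value, ambient_value, unit = NULL,
                              ambient_unit = NULL) {
  if (!is.null(unit) && !is.null(ambient_unit) && !all(unit == ambient_unit)) {
    rlang::abort("enclosure and ambient concentrations must share a unit")
  }
  cpe_value - ambient_value
}

#' Emission flux for one sampling period
#'
#' Ideal-gas conversion of a mean net concentration to a mass emission rate:
#'
#' \deqn{flux = \frac{net \times airflow \times 1000}
#'   {V_s \times (T + 273.15)/273.15} \times MW / D}
#'
#' with \eqn{V_s = 22.4} L/mol, MW the species molecular weight and D the
#' unit-standardizing denominator (1e6 for mg/L species, 1e9 for ug/L
#' species). The sign of the flux follows the net concentration.
#'
#' @param net_conc Mean net concentration over the period, in the species'
#'   native unit (ug/L for NH3 and H2S, mg/L otherwise).
#' @param gas Character vector of species names (`"NH3"`, `"CH4"`, `"CO2"`,
#'   `"H2S"`, `"N2O"`).
#' @param airflow_m3_min Enclosure airflow (m^3/min), > 0.
#' @param temp_c Sample temperature (deg C), > -273.15.
#' @return Flux in g/min.
#' @export
#' @examples
#' period_flux(100, "NH3", 60, 20) # ~4.25e-3 g/min
period_flux <- function(net_conc, gas, airflow_m3_min, temp_c) {
  if (any(airflow_m3_min <= 0)) rlang::abort("airflow must be strictly positive")
  k <- flux_constants()
  if (any(temp_c <= -k$kelvin_offset)) rlang::abort("temperature below absolute zero")
  sp <- species_info(gas)
  vs_t <- k$vs_l_mol * (temp_c + k$kelvin_offset) / k$kelvin_offset
  net_conc * airflow_m3_min * k$litres_per_m3 / vs_t * sp$mw / sp$denominator
}

#' Invert the flux equation to a net concentration
#'
#' Given a target emission rate, airflow and temperature, return the net
#' concentration (species' native unit) that [period_flux()] maps back to
#' that rate. Used by the synthetic generator so that simulated analyzer
#' readings are exactly consistent with the flux model.
#'
#' @inheritParams period_flux
#' @param flux_g_min Emission rate in g/min.
#' @return Net concentration in the species' native unit.
#' @export
concentration_for_flux <- function(flux_g_min, gas, airflow_m3_min, temp_c) {
  if (any(airflow_m3_min <= 0)) rlang::abort("airflow must be strictly positive")
  k <- flux_constants()
  sp <- species_info(gas)
  vs_t <- k$vs_l_mol * (temp_c + k$kelvin_offset) / k$kelvin_offset
  flux_g_min * sp$denominator * vs_t / (airflow_m3_min * k$litres_per_m3 * sp$mw)
}
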