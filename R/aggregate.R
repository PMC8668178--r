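#' Per-period emission fluxes from summarised readings
#'
#' Pairs each valid enclosure sampling period with the most recent valid
#' ambient period of the same gas (the rotation samples ambient air at the
#' head of every sweep, so this is the ambient reading of the current sweep;
#' the nearest later ambient period is used if none precedes), forms the net
#' concentration, and converts it to g/min with [period_flux()] using the
#' fan-decay airflow at the period midpoint and the period-mean enclosure
#' temperature.
#'
#' @param periods Period table from [summarize_periods()].
#' @param fans Fan calibration table with columns `cycle`, `cpe_id`,
#'   `fan_id`, `t0`, `t1`, `flow_start`, `flow_end`.
#' @return Tibble of enclosure periods with `ambient_value`, `net_conc`,
#'   `airflow`, `flux_g_min` (NA for invalid periods) added.
#' @export
compute_period_fluxes <- function(periods, fans) {
  cpe <- dplyr::filter(periods, .data$source != "ambient")
  amb <- dplyr::filter(periods, .data$source == "ambient", .data$is_valid)

  cpe <- cpe %>%
    dplyr::group_by(.data$cycle, .data$gas) %>%
    dplyr::group_modify(function(df, key) {
      a <- amb[amb$cycle == key$cycle & amb$gas == key$gas, ]
      a <- a[order(a$period), ]
      if (nrow(a) == 0) {
        rlang::abort(sprintf(
          "no valid ambient periods for %s in cycle %s", key$gas, key$cycle
        ))
      }
      idx <- findInterval(df$period, a$period)
      idx[idx == 0] <- 1L # nothing earlier: use the nearest later sweep
      df$ambient_value <- a$mean_value[idx]
      df
    }) %>%
    dplyr::ungroup()

  cpe <- cpe %>%
    dplyr::group_by(.data$cycle, .data$source) %>%
    dplyr::group_modify(function(df, key) {
      f <- fans[fans$cycle == key$cycle & fans$cpe_id == key$source, ]
      if (nrow(f) == 0) {
        rlang::abort(sprintf("no fan calibrations for %s", key$source))
      }
      df$airflow <- airflow_at(f, df$t_mid)
      df
    }) %>%
    dplyr::ungroup() %>%
    dplyr::rename(cpe_id = "source")

  cpe %>%
    dplyr::mutate(
      net_conc = net_concentration(.data$mean_value, .data$ambient_value),
      flux_g_min = ifelse(
        .data$is_valid,
        period_flux(
          ifelse(.data$is_valid, .data$net_conc, 0), .data$gas,
          .data$airflow, ifelse(.data$is_valid, .data$mean_temp_c, 20)
        ),
        NA_real_
      )
    )
}

#' Daily per-animal emissions
#'
#' Averages the valid period fluxes of each enclosure gas-day (0800-anchored),
#' scales by 1,440 min to a daily mass, and divides by the number of cattle
#' present that day. Days with fewer than four valid periods get `NA` and are
#' routed to [substitute_missing()].
#'
#' @param fluxes Period flux table from [compute_period_fluxes()].
#' @param inventory Per-day headcount table with columns `cycle`, `cpe_id`,
#'   `day`, `headcount`.
#' @return Tibble keyed by (cycle, cpe_id, gas, day): `mean_flux`,
#'   `n_valid`, `headcount`, `g_per_animal`, `substituted` (all `FALSE`;
#'   set by substitution).
#' @export
daily_emissions <- function(fluxes, inventory) {
  out <- fluxes %>%
    dplyr::group_by(.data$cycle, .data$cpe_id, .data$gas, .data$day) %>%
    dplyr::summarise(
      mean_flux = ifelse(any(.data$is_valid),
        mean(.data$flux_g_min[.data$is_valid]), NA_real_
      ),
      n_valid = sum(.data$is_valid),
      .groups = "drop"
    ) %>%
    dplyr::left_join(inventory, by = c("cycle", "cpe_id", "day"))
  if (anyNA(out$headcount)) {
    rlang::abort("inventory is missing headcounts for some enclosure-days")
  }
  if (any(out$headcount <= 0)) rlang::abort("headcount must be positive")
  out %>%
    dplyr::mutate(
      g_per_animal = ifelse(.data$n_valid >= .MIN_VALID_PERIODS,
        .data$mean_flux * .MINUTES_PER_DAY / .data$headcount, NA_real_
      ),
      substituted = FALSE
    )
}

#' Cumulative per-animal emissions over interim intervals
#'
#' Sums daily per-animal emissions over the intervals ending at each interim
#' body-weight day. An interval labelled "0-N" covers the N complete
#' 0800-anchored days 0..N-1; the full 0-91 window therefore covers days
#' 0..90 (measurements stop at 0500 h on day 91, before a complete day 91).
#'
#' @param daily Daily emission table, post-substitution (no `NA` days).
#' @param intervals Integer vector of interval end days (default the interim
#'   weigh days 7, 14, 28, 56 and the 91-d total).
#' @return Tibble keyed by (cycle, cpe_id, gas, interval_end) with `interval`
#'   label and `total_g` per animal.
#' @export
cumulative_emissions <- function(daily, intervals = c(7, 14, 28, 56, 91)) {
  if (anyNA(daily$g_per_animal)) {
    rlang::abort("daily series contains unresolved missing days; run substitute_missing() first")
  }
  purrr::map_dfr(intervals, function(n) {
    sub <- dplyr::filter(daily, .data$day < n)
    have <- sub %>%
      dplyr::group_by(.data$cycle, .data$cpe_id, .data$gas) %>%
      dplyr::summarise(
        n_days = dplyr::n_distinct(.data$day),
        total_g = sum(.data$g_per_animal), .groups = "drop"
      )
    if (any(have$n_days != n)) {
      rlang::abort(sprintf("interval 0-%d is missing days in some enclosures", n))
    }
    dplyr::mutate(have,
      interval = sprintf("0-%d", n), interval_end = n,
      n_days = NULL
    )
  })
}

#' Standardize a cumulative emission by a body or carcass weight
#'
#' @param cum_g Cumulative emission (g/animal).
#' @param weight_kg Standardizing weight (kg), > 0: the enclosure mean
#'   unshrunk BW at the interval-end weigh day, or the enclosure mean hot
#'   carcass weight for the 91-d carcass standardization.
#' @return g/kg. Scale-equivariant: `standardize(k*g, k*w) = standardize(g, w)`.
#' @export
standardize <- function(cum_g, weight_kg) {
  if (any(weight_kg <= 0)) rlang::abort("standardizing weight must be positive")
  cum_g / weight_kg
}

#' Weight-standardized cumulative emissions
#'
#' Divides each enclosure's cumulative emission by the enclosure mean
#' unshrunk BW measured at the interval-end day, and (for the final
#' interval, 0-91 in the standard design) by the enclosure mean hot carcass
#' weight.
#'
#' @param cum Cumulative emissions from [cumulative_emissions()].
#' @param bw Body-weight table with columns `cycle`, `cpe_id`, `animal_id`,
#'   `day`, `bw_kg` (weigh days must include each interval end).
#' @param carcass Optional carcass table with `cycle`, `cpe_id`, `hcw_kg`.
#' @return `cum` with `mean_bw_kg`, `per_kg_bw` and (where available)
#'   `mean_hcw_kg`, `per_kg_hcw` columns.
#' @export
standardize_emissions <- function(cum, bw, carcass = NULL) {
  pen_bw <- bw %>%
    dplyr::group_by(.data$cycle, .data$cpe_id, .data$day) %>%
    dplyr::summarise(mean_bw_kg = mean(.data$bw_kg), .groups = "drop")
  out <- cum %>%
    dplyr::left_join(pen_bw, by = c("cycle", "cpe_id", interval_end = "day"))
  if (anyNA(out$mean_bw_kg)) {
    rlang::abort("no body weights recorded at some interval-end days")
  }
  out <- dplyr::mutate(out, per_kg_bw = standardize(.data$total_g, .data$mean_bw_kg))
  if (!is.null(carcass)) {
    pen_hcw <- carcass %>%
      dplyr::group_by(.data$cycle, .data$cpe_id) %>%
      dplyr::summarise(mean_hcw_kg = mean(.data$hcw_kg), .groups = "drop")
    out <- out %>%
      dplyr::left_join(pen_hcw, by = c("cycle", "cpe_id")) %>%
      dplyr::mutate(per_kg_hcw = ifelse(
        .data$interval_end == max(.data$interval_end),
        standardize(.data$total_g, .data$mean_hcw_kg), NA_real_
      ))
  }
  out
}
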