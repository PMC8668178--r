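#' Flag analyzer readings disturbed by door or bunk-flap events
#'
#' Opening the large door or the feed-bunk flaps of an enclosure disrupts the
#' steady-state gas equilibrium, so all readings of the affected enclosure
#' from 5 min before the opening until 15 min after the closing are excluded
#' from flux calculations. Small-door entries disturb airflow negligibly and
#' exclude nothing. Overlapping windows union naturally (exclusion is a
#' set-membership flag), which also makes the operation idempotent.
#'
#' @param readings Reading table with columns `cycle`, `timestamp`, `source`,
#'   `gas`, `value` (and optionally an existing logical `excluded`).
#' @param events Event log with columns `cycle`, `cpe_id`,
#'   `kind` (`"large_door"`, `"bunk_flap"` or `"small_door"`), `open_time`,
#'   `close_time` (seconds).
#' @return `readings` with a logical `excluded` column.
#' @export
mark_exclusions <- function(readings, events) {
  if (!"excluded" %in% names(readings)) readings$excluded <- FALSE
  if (nrow(events) == 0) return(readings)
  known <- c("large_door", "bunk_flap", "small_door")
  if (!all(events$kind %in% known)) {
    rlang::abort(paste0(
      "unknown event kind: ",
      paste(setdiff(unique(events$kind), known), collapse = ", ")
    ))
  }
  if (any(events$close_time < events$open_time)) {
    rlang::abort("event close_time must be >= open_time")
  }
  disruptive <- events[events$kind %in% c("large_door", "bunk_flap"), ]
  for (i in seq_len(nrow(disruptive))) {
    ev <- disruptive[i, ]
    hit <- readings$cycle == ev$cycle &
      readings$source == ev$cpe_id &
      readings$timestamp >= ev$open_time - 300 &
      readings$timestamp <= ev$close_time + 900
    readings$excluded <- readings$excluded | hit
  }
  readings
}

#' Is a sampling period valid?
#'
#' A 15-min period is valid when at least 4 min of non-excluded data remain,
#' i.e. at least 16 readings at the 15-s cadence (boundary inclusive).
#'
#' @param n_ok Integer vector: non-excluded readings in the period.
#' @return Logical vector.
#' @export
period_validity <- function(n_ok) {
  n_ok >= .MIN_VALID_READINGS
}

#' Summarise readings into sampling periods
#'
#' Collapses the 15-s reading stream into one row per 15-min sampling period
#' per source, gas and cycle, carrying the mean concentration and temperature
#' over non-excluded readings, the minutes of usable data, and the validity
#' flag. A period is assigned to the 0800-anchored day containing its start
#' time.
#'
#' @param readings Reading table (see [mark_exclusions()]); an `excluded`
#'   column is honoured and assumed `FALSE` when absent.
#' @return Tibble with one row per (cycle, source, gas, period):
#'   `t_start`, `t_mid`, `day`, `n_readings`, `n_ok`, `valid_minutes`,
#'   `is_valid`, `mean_value`, `mean_temp_c`, `unit`.
#' @export
summarize_periods <- function(readings) {
  if (!"excluded" %in% names(readings)) readings$excluded <- FALSE
  readings %>%
    dplyr::mutate(period = floor(.data$timestamp / .SECONDS_PER_PERIOD)) %>%
    dplyr::group_by(.data$cycle, .data$source, .data$gas, .data$period) %>%
    dplyr::summarise(
      t_start = min(.data$timestamp),
      n_readings = dplyr::n(),
      n_ok = sum(!.data$excluded),
      mean_value = ifelse(sum(!.data$excluded) > 0,
        mean(.data$value[!.data$excluded]), NA_real_
      ),
      mean_temp_c = ifelse(sum(!.data$excluded) > 0,
        mean(.data$temp_c[!.data$excluded]), NA_real_
      ),
      unit = .data$unit[1],
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      t_mid = (.data$period + 0.5) * .SECONDS_PER_PERIOD,
      day = floor(.data$period * .SECONDS_PER_PERIOD / .SECONDS_PER_DAY),
      valid_minutes = .data$n_ok * .SECONDS_PER_READING / 60,
      is_valid = period_validity(.data$n_ok)
    )
}

#' Substitute unrecoverable gas-days by the neighbour-day mean
#'
#' A gas-day with fewer than four valid sampling periods cannot support a
#' daily value. Its per-animal daily emission is replaced by the arithmetic
#' mean of the two days before and the two days after (for a failure on day
#' 7: days 5, 6, 8 and 9). All four neighbour days must exist and be valid;
#' no deeper fallback exists, so a missing or invalid neighbour is an error.
#'
#' @param daily Daily emission table from [daily_emissions()] with columns
#'   `cycle`, `cpe_id`, `gas`, `day`, `g_per_animal`, `n_valid`,
#'   `substituted`.
#' @return `daily` with invalid days filled and flagged `substituted`.
#' @export
substitute_missing <- function(daily) {
  daily <- dplyr::arrange(daily, .data$cycle, .data$cpe_id, .data$gas, .data$day)
  bad <- which(daily$n_valid < .MIN_VALID_PERIODS)
  for (i in bad) {
    key <- daily[i, c("cycle", "cpe_id", "gas")]
    neighbours <- daily$cycle == key$cycle & daily$cpe_id == key$cpe_id &
      daily$gas == key$gas & daily$day %in% (daily$day[i] + c(-2, -1, 1, 2))
    ok <- neighbours & daily$n_valid >= .MIN_VALID_PERIODS
    if (sum(ok) < 4) {
      rlang::abort(sprintf(
        "unrecoverable day: %s %s %s day %d lacks four valid neighbour days",
        key$cycle, key$cpe_id, key$gas, daily$day[i]
      ))
    }
    daily$g_per_animal[i] <- mean(daily$g_per_animal[ok])
    daily$substituted[i] <- TRUE
  }
  daily
}

#' Per gas-day validity report
#'
#' @param daily Daily emission table (post-substitution or not).
#' @return Tibble keyed by (cycle, cpe_id, gas, day) with `n_valid` and
#'   `substituted`.
#' @export
validity_report <- function(daily) {
  dplyr::select(
    daily, "cycle", "cpe_id", "gas", "day", "n_valid", "substituted"
  )
}
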