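#' Dry-matter intake per animal per day
#'
#' Total as-fed feed delivered less refused feed (orts), divided by the
#' cumulative cattle-days in the pen, scaled by the diet dry-matter fraction.
#'
#' @param delivered_asfed_kg Total as-fed delivery (kg).
#' @param orts_asfed_kg As-fed refusals at the end of the period (kg).
#' @param cattle_days Cumulative animal-days over the period, > 0.
#' @param dm_fraction Diet dry-matter fraction in (0, 1].
#' @return DMI in kg DM per animal per day.
#' @export
#' @examples
#' compute_dmi(100, 0, 10, 0.765) # 7.65
compute_dmi <- function(delivered_asfed_kg, orts_asfed_kg, cattle_days,
                        dm_fraction) {
  if (any(cattle_days <= 0)) rlang::abort("cattle_days must be positive")
  if (any(dm_fraction <= 0 | dm_fraction > 1)) {
    rlang::abort("dm_fraction must be in (0, 1]")
  }
  if (any(orts_asfed_kg > delivered_asfed_kg)) {
    rlang::abort("orts cannot exceed feed delivered")
  }
  (delivered_asfed_kg - orts_asfed_kg) / cattle_days * dm_fraction
}

#' USDA continuous yield grade
#'
#' `YG = 2.50 + 0.98 * fat(cm) + 0.2 * KPH(%) + 0.0084 * HCW(kg)
#'  - 0.05 * LM area(cm^2)`, unrounded.
#'
#' @param adj_fat_cm Adjusted 12th-rib fat thickness (cm).
#' @param kph_pct Kidney, pelvic and heart fat (% of carcass weight).
#' @param hcw_kg Hot carcass weight (kg).
#' @param lm_cm2 Longissimus (ribeye) area (cm^2).
#' @return Continuous yield grade.
#' @export
yield_grade <- function(adj_fat_cm, kph_pct, hcw_kg, lm_cm2) {
  if (any(c(adj_fat_cm, kph_pct, hcw_kg, lm_cm2) < 0)) {
    rlang::abort("yield grade inputs must be non-negative")
  }
  2.50 + 0.98 * adj_fat_cm + 0.2 * kph_pct + 0.0084 * hcw_kg - 0.05 * lm_cm2
}

#' Discrete yield-grade class
#'
#' Floor of the continuous grade, clamped to 1..5 (YG 1 = 1.00-1.99,
#' YG 2 = 2.00-2.99, and so on).
#'
#' @param yg_continuous Continuous yield grade.
#' @return Integer class in 1..5.
#' @export
yield_grade_class <- function(yg_continuous) {
  pmin(pmax(floor(yg_continuous), 1L), 5L)
}

#' Temperature-humidity index
#'
#' `THI = 0.8 * TA + (RH/100) * (TA - 14.4) + 46.4`, the standard cattle
#' heat-stress index combining ambient temperature and relative humidity.
#'
#' @param ta_c Ambient temperature (deg C).
#' @param rh_pct Relative humidity (0-100).
#' @return THI (unitless index).
#' @export
#' @examples
#' thi(30, 50) # 78.2
thi <- function(ta_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100)) rlang::abort("rh_pct must be in [0, 100]")
  0.8 * ta_c + (rh_pct * 0.01) * (ta_c - 14.4) + 46.4
}

#' Marketing-grid quality class
#'
#' Maps a marbling score (100 points per degree; 500 = Small^00) to the five
#' grid-pricing categories for A-maturity carcasses: >= 700 Prime, 600-699
#' upper 2/3 Choice, 500-599 low Choice, 400-499 Select, < 400 Standard.
#' Breakpoints follow the standard USDA marbling-degree boundaries.
#'
#' @param marbling Marbling score (>= 0).
#' @param overall_maturity Overall maturity (100 = A^0); must be < 300
#'   (A or B maturity) — older-carcass grading logic is out of scope.
#' @return Factor with levels Prime, upper 2/3 Choice, low Choice, Select,
#'   Standard.
#' @export
#' @examples
#' quality_class(623) # upper 2/3 Choice
quality_class <- function(marbling, overall_maturity = 150) {
  if (any(marbling < 0)) rlang::abort("marbling must be non-negative")
  if (any(overall_maturity >= 300)) {
    rlang::abort("quality_class supports only A/B maturity carcasses")
  }
  lev <- c("Prime", "upper 2/3 Choice", "low Choice", "Select", "Standard")
  cls <- dplyr::case_when(
    marbling >= 700 ~ "Prime",
    marbling >= 600 ~ "upper 2/3 Choice",
    marbling >= 500 ~ "low Choice",
    marbling >= 400 ~ "Select",
    TRUE ~ "Standard"
  )
  factor(cls, levels = lev)
}

#' Warner-Bratzler shear force of a steak
#'
#' Arithmetic mean of the peak shear force of exactly six cores.
#'
#' @param core_forces_kg Numeric vector of six peak core forces (kg).
#' @return Mean shear force (kg).
#' @export
wbsf_mean <- function(core_forces_kg) {
  if (length(core_forces_kg) != 6) {
    rlang::abort("WBSF requires exactly 6 cores per steak")
  }
  mean(core_forces_kg)
}

#' Pen-level growth performance and carcass summary
#'
#' Computes, per enclosure: initial/final mean unshrunk BW, ADG over the
#' 91-d period, DMI from total deliveries, orts and cattle-days, G:F
#' (ADG/DMI), mean HCW and dressing percent (100 * HCW / final BW).
#' All quantities are pen means — the enclosure is the experimental unit.
#'
#' @param bw Body-weight table (`cycle`, `cpe_id`, `animal_id`, `day`,
#'   `bw_kg`) including days 0 and `final_day`.
#' @param feed Feed table (`cycle`, `cpe_id`, `delivered_asfed_kg` per day and
#'   a terminal `orts_asfed_kg`); summed within pen.
#' @param inventory Per-day headcount (`cycle`, `cpe_id`, `day`, `headcount`).
#' @param carcass Carcass table (`cycle`, `cpe_id`, `hcw_kg`, ...).
#' @param dm_fraction Diet dry-matter fraction.
#' @param final_day Final weigh day (default 91).
#' @return Tibble keyed by (cycle, cpe_id) with `initial_bw`, `final_bw`,
#'   `adg`, `dmi`, `gf`, `mean_hcw`, `dressing_pct`.
#' @export
pen_performance <- function(bw, feed, inventory, carcass, dm_fraction = 0.765,
                            final_day = 91) {
  bw_sum <- bw %>%
    dplyr::filter(.data$day %in% c(0, final_day)) %>%
    dplyr::group_by(.data$cycle, .data$cpe_id, .data$day) %>%
    dplyr::summarise(mean_bw = mean(.data$bw_kg), .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "day", values_from = "mean_bw",
      names_prefix = "bw_"
    ) %>%
    dplyr::rename(initial_bw = "bw_0", final_bw = paste0("bw_", final_day))

  feed_sum <- feed %>%
    dplyr::group_by(.data$cycle, .data$cpe_id) %>%
    dplyr::summarise(
      delivered = sum(.data$delivered_asfed_kg),
      orts = sum(.data$orts_asfed_kg),
      .groups = "drop"
    )
  cd <- inventory %>%
    dplyr::filter(.data$day < final_day) %>%
    dplyr::group_by(.data$cycle, .data$cpe_id) %>%
    dplyr::summarise(cattle_days = sum(.data$headcount), .groups = "drop")
  hcw <- carcass %>%
    dplyr::group_by(.data$cycle, .data$cpe_id) %>%
    dplyr::summarise(mean_hcw = mean(.data$hcw_kg), .groups = "drop")

  bw_sum %>%
    dplyr::left_join(feed_sum, by = c("cycle", "cpe_id")) %>%
    dplyr::left_join(cd, by = c("cycle", "cpe_id")) %>%
    dplyr::left_join(hcw, by = c("cycle", "cpe_id")) %>%
    dplyr::mutate(
      adg = (.data$final_bw - .data$initial_bw) / final_day,
      dmi = compute_dmi(.data$delivered, .data$orts, .data$cattle_days, dm_fraction),
      gf = .data$adg / .data$dmi,
      dressing_pct = 100 * .data$mean_hcw / .data$final_bw
    ) %>%
    dplyr::select(
      "cycle", "cpe_id", "initial_bw", "final_bw", "adg", "dmi", "gf",
      "mean_hcw", "dressing_pct"
    )
}
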