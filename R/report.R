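#' Percent reduction relative to control
#'
#' `100 * (control - treated) / control`, rounded to one decimal for
#' reporting (pass `digits = NULL` for the raw value).
#'
#' @param control_value Control mean, > 0.
#' @param treated_value Treated mean(s).
#' @param digits Decimals for reporting (default 1).
#' @return Percent reduction (negative if the treated mean is larger).
#' @export
#' @examples
#' percent_reduction(7783, 6751) # 13.3
percent_reduction <- function(control_value, treated_value, digits = 1) {
  if (any(control_value <= 0)) rlang::abort("control value must be positive")
  out <- 100 * (control_value - treated_value) / control_value
  if (is.null(digits)) out else round(out, digits)
}

#' Percent increase relative to control
#'
#' @inheritParams percent_reduction
#' @return Percent increase (negative if the treated mean is smaller).
#' @export
percent_increase <- function(control_value, treated_value, digits = 1) {
  out <- -percent_reduction(control_value, treated_value, digits = NULL)
  if (is.null(digits)) out else round(out, digits)
}

#' Nitrogen-conservation equivalence chain
#'
#' Translates a cumulative NH3 emission reduction into its nitrogen,
#' carcass-protein and carcass-mass equivalents: ammonia is 82.2% N,
#' carcass protein is 16% N, and protein averages 16.5% of retail beef, so
#' 1,000 g of avoided NH3 carries the N of ~5,138 g of protein or ~31.1 kg
#' of carcass. When an observed carcass-weight gain is supplied, the
#' theoretical efficiency of N conservation is the observed gain as a
#' percentage of the carcass equivalent, computed — as in the published
#' worked example — with the carcass-equivalence factor rounded to its
#' reported precision (31.1 kg per kg NH3).
#'
#' @param nh3_reduction_g Cumulative NH3 reduction (g/animal), >= 0.
#' @param hcw_gain_kg Observed hot-carcass-weight gain (kg/animal), optional.
#' @return Tibble with `nh3_reduction_g`, `n_conserved_g`,
#'   `protein_equiv_g`, `carcass_equiv_kg` and (if a gain is given)
#'   `efficiency_pct`.
#' @export
#' @examples
#' n_conservation(1000) # 822 g N, 5137.5 g protein, ~31.1 kg carcass
n_conservation <- function(nh3_reduction_g, hcw_gain_kg = NULL) {
  if (any(nh3_reduction_g < 0)) rlang::abort("NH3 reduction must be non-negative")
  nh3_n <- 0.822 # N fraction of ammonia
  protein_n <- 0.16 # N fraction of protein
  carcass_protein <- 0.165 # protein fraction of retail beef
  n_conserved <- nh3_reduction_g * nh3_n
  protein_equiv <- n_conserved / protein_n
  carcass_equiv <- protein_equiv / carcass_protein / 1000
  out <- tibble::tibble(
    nh3_reduction_g = nh3_reduction_g,
    n_conserved_g = n_conserved,
    protein_equiv_g = protein_equiv,
    carcass_equiv_kg = carcass_equiv
  )
  if (!is.null(hcw_gain_kg)) {
    factor_rounded <- round(nh3_n / protein_n / carcass_protein, 1) # kg/kg
    out$efficiency_pct <- ifelse(
      nh3_reduction_g > 0,
      100 * hcw_gain_kg / (nh3_reduction_g / 1000 * factor_rounded),
      NA_real_
    )
  }
  out
}

#' Reference trial summary tables
#'
#' Least-squares-mean summary tables of the 91-d dose-titration reference
#' trial (cumulative emissions, interim NH3 emissions, growth performance
#' and carcass characteristics), shipped as plain-text fixtures so the
#' worked-example calculators run without transcription. Contrast p-values
#' printed as bounds ("<0.001") are stored as their upper bounds.
#'
#' @return Named list of tibbles: `emissions_91d`, `nh3_interim`,
#'   `performance`.
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", "reference_trial", package = "penflux")
  read1 <- function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE, comment = "#")
  }
  list(
    emissions_91d = read1("emissions_91d.csv"),
    nh3_interim = read1("nh3_interim.csv"),
    performance = read1("performance.csv")
  )
}

#' Worked-example quantities from the reference summary tables
#'
#' Recomputes, from the packaged least-squares means alone, the headline
#' arithmetic of the reference trial: cumulative and weight-standardized
#' NH3 percent reductions per dose, interim-period reductions, absolute
#' gram reductions, carcass-weight increases, G:F and ADG percent
#' increases, and the nitrogen-conservation chain.
#'
#' @param tables Tables as returned by [reference_tables()].
#' @return Long tibble with `quantity`, `dose` and `value` (percentages in
#'   percent, masses in g or kg as named).
#' @export
worked_examples <- function(tables = reference_tables()) {
  em <- tables$emissions_91d
  pf <- tables$performance
  it <- tables$nh3_interim
  row <- function(df, v) df[df$variable == v, ]
  dose_cols <- c("d1_38", "d5_5", "d22")
  doses <- c(1.38, 5.5, 22.0)
  grab <- function(r) c(r$d1_38, r$d5_5, r$d22)

  nh3 <- row(em, "nh3_total_g")
  nh3_bw <- row(em, "nh3_per_kg_bw")
  nh3_hcw <- row(em, "nh3_per_kg_hcw")
  hcw <- row(em, "hcw_kg")
  gf <- row(pf, "gf")
  adg <- row(pf, "adg_kg")
  d07 <- row(it, "nh3_g_0_7")
  d014 <- row(it, "nh3_g_0_14")

  long <- function(quantity, value, dose = doses) {
    tibble::tibble(quantity = quantity, dose = dose, value = value)
  }
  red_g <- round(nh3$d0 - grab(nh3))
  hcw_gain <- round(grab(hcw) - hcw$d0)
  ncons <- n_conservation(red_g, hcw_gain)

  dplyr::bind_rows(
    long("nh3_cumulative_reduction_pct", percent_reduction(nh3$d0, grab(nh3))),
    long("nh3_per_kg_bw_reduction_pct", percent_reduction(nh3_bw$d0, grab(nh3_bw))),
    long("nh3_per_kg_hcw_reduction_pct", percent_reduction(nh3_hcw$d0, grab(nh3_hcw))),
    long("nh3_reduction_g", red_g),
    long("hcw_increase_kg", hcw_gain),
    long("gf_increase_pct", percent_increase(gf$d0, grab(gf))),
    long("adg_increase_pct", percent_increase(adg$d0, grab(adg))),
    long("interim_0_7_reduction_pct", percent_reduction(d07$d0, d07$d22), 22.0),
    long(
      "interim_0_14_reduction_pct",
      percent_reduction(d014$d0, c(d014$d5_5, d014$d22)), c(5.5, 22.0)
    ),
    long("protein_equiv_g_per_kg_nh3",
      round(n_conservation(1000)$protein_equiv_g),
      dose = NA_real_
    ),
    long("carcass_equiv_kg_per_kg_nh3",
      round(n_conservation(1000)$carcass_equiv_kg, 1),
      dose = NA_real_
    ),
    long("n_conservation_efficiency_pct", round(ncons$efficiency_pct, 1))
  )
}
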