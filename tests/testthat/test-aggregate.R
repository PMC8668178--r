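make_daily <- function(g, days = 91) {
  tibble::tibble(
    cycle = 1, cpe_id = "CPE1", gas = "NH3", day = seq_len(days) - 1,
    mean_flux = NA_real_, n_valid = 11L, headcount = 14,
    g_per_animal = g, substituted = FALSE
  )
}

test_that("daily per-animal emission is mean flux x 1440 / headcount", {
  fluxes <- tibble::tibble(
    cycle = 1, cpe_id = "CPE1", gas = "NH3", day = 0,
    period = 0:10, is_valid = TRUE, flux_g_min = 0.005
  )
  inv <- tibble::tibble(cycle = 1, cpe_id = "CPE1", day = 0, headcount = 14)
  d <- daily_emissions(fluxes, inv)
  expect_equal(d$g_per_animal, 0.005 * 1440 / 14, tolerance = 1e-12)
  expect_equal(d$n_valid, 11L)

  # all-zero fluxes give zero; halving headcount doubles the per-animal value
  expect_equal(
    daily_emissions(dplyr::mutate(fluxes, flux_g_min = 0), inv)$g_per_animal, 0
  )
  d7 <- daily_emissions(fluxes, dplyr::mutate(inv, headcount = 7))
  expect_equal(d7$g_per_animal, 2 * d$g_per_animal)
  expect_error(
    daily_emissions(fluxes, dplyr::mutate(inv, headcount = 0)), "positive"
  )

  # only the valid periods enter the mean
  mixed <- dplyr::mutate(fluxes,
    is_valid = period < 5,
    flux_g_min = ifelse(period < 5, 0.004, 99)
  )
  expect_equal(
    daily_emissions(mixed, inv)$g_per_animal, 0.004 * 1440 / 14
  )
  expect_equal(daily_emissions(mixed, inv)$n_valid, 5L)
})

test_that("cumulative intervals sum days 0..N-1 and are nested", {
  daily <- make_daily(rep(85.5, 91))
  cum <- cumulative_emissions(daily)
  expect_equal(sort(cum$interval_end), c(7, 14, 28, 56, 91))
  expect_equal(cum$total_g[cum$interval_end == 91], 91 * 85.5)
  expect_equal(cum$total_g[cum$interval_end == 7], 7 * 85.5)

  set.seed(3)
  pos <- make_daily(runif(91, 0, 5))
  cpos <- dplyr::arrange(cumulative_emissions(pos), interval_end)
  expect_true(all(diff(cpos$total_g) >= 0)) # monotone for nonnegative series
  expect_equal(
    cpos$total_g[cpos$interval_end == 14],
    sum(pos$g_per_animal[pos$day < 14])
  )

  expect_error(
    cumulative_emissions(make_daily(rep(1, 50), days = 50)), "missing days"
  )
  na_daily <- make_daily(c(NA, rep(1, 90)))
  expect_error(cumulative_emissions(na_daily), "unresolved missing")
})

test_that("weight standardization divides by the pen mean weight at interval end", {
  expect_equal(standardize(7783, 567), 13.72663, tolerance = 1e-6)
  expect_equal(round(standardize(6751, 582), 1), 11.6)
  expect_equal(standardize(0, 500), 0)
  expect_error(standardize(100, 0), "positive")
  # scale equivariance
  expect_equal(standardize(3 * 1234, 3 * 432), standardize(1234, 432))

  daily <- make_daily(rep(10, 91))
  cum <- cumulative_emissions(daily)
  bw <- tidyr::expand_grid(
    cycle = 1, cpe_id = "CPE1", animal_id = c("a1", "a2"),
    day = c(0, 7, 14, 28, 56, 91)
  )
  bw$bw_kg <- 450 + 1.4 * bw$day + ifelse(bw$animal_id == "a1", -10, 10)
  carcass <- tibble::tibble(
    cycle = 1, cpe_id = "CPE1", hcw_kg = c(350, 360)
  )
  std <- standardize_emissions(cum, bw, carcass)
  expect_equal(
    std$per_kg_bw[std$interval_end == 56],
    56 * 10 / (450 + 1.4 * 56)
  )
  expect_equal(
    std$per_kg_hcw[std$interval_end == 91], 91 * 10 / 355
  )
  expect_true(is.na(std$per_kg_hcw[std$interval_end == 7]))
})

test_that("continuous rotation is diurnal-unbiased; a daytime-only schedule is not", {
  cfg <- trial_config(
    days = 2, n_cycles = 1, gases = "NH3", seed = 13,
    effects = noiseless_effects(
      nh3_dose_mult = c(1, 1, 1, 1), diurnal_amplitude = 0.3
    )
  )
  tr <- simulate_trial(cfg)
  fluxes <- compute_period_fluxes(summarize_periods(tr$readings), tr$fans)
  rate <- expected_daily_emission(cfg$effects, "NH3")

  # day 0 is a complete 0800-0759 day; day 1 is truncated at 0500 and may
  # over-represent non-trough hours, so only complete days are judged
  full <- daily_emissions(fluxes, tr$inventory)
  full0 <- full[full$day == 0, ]
  expect_true(all(abs(full0$g_per_animal / rate - 1) < 0.01))

  # sampling only 0800-2000 (peak emission at 1400) inflates the estimate:
  # the mean diurnal factor over that window is 1 + 0.3 * 2/pi ~ 1.19
  hour <- ((fluxes$t_mid + 8 * 3600) %% 86400) / 3600
  daytime <- daily_emissions(fluxes[hour >= 8 & hour < 20, ], tr$inventory)
  expect_true(all(daytime$g_per_animal[daytime$day == 0] / rate > 1.1))
})

test_that("zero-noise end-to-end run conserves the generated emission rate", {
  cfg <- trial_config(
    days = 3, n_cycles = 1, gases = "NH3", seed = 5,
    effects = noiseless_effects(nh3_dose_mult = c(1, 1, 1, 1))
  )
  tr <- simulate_trial(cfg)
  periods <- summarize_periods(mark_exclusions(tr$readings, tr$events))
  daily <- daily_emissions(compute_period_fluxes(periods, tr$fans), tr$inventory) %>%
    substitute_missing()
  cum <- cumulative_emissions(daily, intervals = 3)
  expect_equal(nrow(daily), 8 * 3)
  # ~10.7 periods/enclosure/day on the 9-source rotation (last day ends 0500)
  expect_true(all(daily$n_valid >= 9 & daily$n_valid <= 11))
  rate <- expected_daily_emission(cfg$effects, "NH3")
  expect_equal(cum$total_g, rep(3 * rate, 8), tolerance = 1e-9)
})
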