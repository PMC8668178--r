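small_cfg <- function(days = 2, n_cycles = 1, gases = "NH3", seed = 42, ...) {
  trial_config(
    days = days, n_cycles = n_cycles, gases = gases, seed = seed,
    effects = effect_model(...)
  )
}

test_that("the generator is bit-reproducible under a fixed seed", {
  t1 <- simulate_trial(small_cfg())
  t2 <- simulate_trial(small_cfg())
  expect_identical(t1$readings, t2$readings)
  expect_identical(t1$carcass, t2$carcass)
  expect_identical(t1$truth$daily, t2$truth$daily)
  t3 <- simulate_trial(small_cfg(seed = 43))
  expect_false(identical(t1$readings$value, t3$readings$value))
})

test_that("the design allocates each dose-by-sex cell once per cycle", {
  tr <- simulate_trial(small_cfg(n_cycles = 3, days = 1), readings = FALSE)
  counts <- dplyr::count(tr$allocation, dose, sex)
  expect_equal(nrow(counts), 8)
  expect_true(all(counts$n == 3))
  percpe <- dplyr::count(tr$allocation, cycle, cpe_id)
  expect_true(all(percpe$n == 1))
  expect_equal(nrow(tr$allocation), 24)
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(doses = c(1.38, 5.5, 22)), "dose 0")
  expect_error(trial_config(doses = c(0, 5.5, 1.38, 22)), "ascending")
  expect_error(trial_config(gases = "O3"), "unknown gas")
  expect_error(
    trial_config(effects = effect_model(nh3_dose_mult = c(1, 0.9))),
    "one entry per dose"
  )
  expect_error(effect_model(nh3_dose_mult = c(0.9, 1, 1, 1)), "dose 0")
  expect_error(effect_model(nh3_dose_mult = c(1, 1.1, 1, 1)), "<= 1")
  expect_error(effect_model(not_a_knob = 3), "unknown")
})

test_that("readings respect the rotation: one source per instant, full cadence", {
  tr <- simulate_trial(small_cfg(days = 1))
  per_instant <- dplyr::count(tr$readings, timestamp, gas)
  expect_true(all(per_instant$n == 1))
  ticks <- sort(unique(tr$readings$timestamp))
  expect_equal(ticks, seq(0, 86400 - 3 * 3600 - 15, by = 15))
  # within a period the source is constant and follows the 9-source cycle
  src <- tr$readings %>%
    dplyr::mutate(period = floor(timestamp / 900)) %>%
    dplyr::distinct(period, source)
  expect_equal(nrow(src), length(unique(src$period)))
  expect_equal(
    src$source[order(src$period)][1:10],
    c("ambient", paste0("CPE", 1:8), "ambient")
  )
})

test_that("a null generator produces identical expected emissions everywhere", {
  cfg <- small_cfg(days = 3, n_cycles = 2,
    reading_noise_cv = 0, day_cv = 0, pen_cv = 0, cycle_cv = 0,
    nh3_dose_mult = c(1, 1, 1, 1)
  )
  tr <- simulate_trial(cfg, readings = FALSE)
  expect_equal(
    tr$truth$daily$rate_g_animal_day,
    rep(85.5, nrow(tr$truth$daily))
  )
})

test_that("Monte-Carlo generator means match the analytic effect model", {
  # mean-one lognormal noise: analytic mean = base rate x dose multiplier
  rates <- purrr::map_dfr(1:20, function(s) {
    tr <- simulate_trial(
      trial_config(days = 91, n_cycles = 1, gases = "NH3", seed = 1000 + s),
      readings = FALSE
    )
    dplyr::summarise(
      dplyr::group_by(tr$truth$daily, dose),
      rate = mean(rate_g_animal_day), .groups = "drop"
    )
  })
  em <- effect_model()
  for (i in seq_along(c(0, 1.38, 5.5, 22))) {
    d <- c(0, 1.38, 5.5, 22)[i]
    obs <- rates$rate[rates$dose == d]
    expected <- expected_daily_emission(em, "NH3", i)
    se <- sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - expected), 3 * se + 1e-9)
  }
})

test_that("the injected NH3 dose multiplier is recovered from cumulative truth", {
  ratios <- purrr::map_dbl(1:20, function(s) {
    tr <- simulate_trial(
      trial_config(days = 91, n_cycles = 1, gases = "NH3", seed = 2000 + s),
      readings = FALSE
    )
    cum <- tr$truth$daily %>%
      dplyr::group_by(cpe_id, dose) %>%
      dplyr::summarise(total = sum(rate_g_animal_day), .groups = "drop")
    mean(cum$total[cum$dose == 22]) / mean(cum$total[cum$dose == 0])
  })
  target <- effect_model()$nh3_dose_mult[4]
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - target), 3 * se + 0.005)
})

test_that("headcount tracks removals, never increases, and respects the floor", {
  cfg <- small_cfg(days = 60, n_cycles = 2, removal_hazard = 5e-3)
  tr <- simulate_trial(cfg, readings = FALSE)
  by_pen <- split(tr$inventory, paste(tr$inventory$cycle, tr$inventory$cpe_id))
  for (pen in by_pen) {
    pen <- pen[order(pen$day), ]
    expect_true(all(diff(pen$headcount) <= 0))
    expect_true(all(pen$headcount >= 10))
    expect_true(all(pen$headcount <= 14))
  }
  expect_true(any(tr$inventory$headcount < 14)) # hazard actually bites
})

test_that("an injected analyzer failure invalidates the day and substitution repairs it", {
  cfg <- trial_config(
    days = 10, n_cycles = 1, gases = "CH4", seed = 8,
    effects = effect_model(
      bunk_flap_rate = 0, large_door_rate = 0, small_door_rate = 0,
      removal_hazard = 0
    )
  )
  tr <- simulate_trial(cfg)
  tr_fail <- inject_analyzer_failure(tr, gas = "CH4", day = 7)

  run_daily <- function(trial) {
    periods <- summarize_periods(mark_exclusions(trial$readings, trial$events))
    daily_emissions(compute_period_fluxes(periods, trial$fans), trial$inventory)
  }
  daily <- run_daily(tr_fail)
  day7 <- daily[daily$day == 7, ]
  expect_true(all(day7$n_valid < 4))
  expect_true(all(is.na(day7$g_per_animal)))

  fixed <- substitute_missing(daily)
  expect_true(all(fixed$substituted[fixed$day == 7]))
  for (cpe in unique(fixed$cpe_id)) {
    sub <- fixed[fixed$cpe_id == cpe, ]
    expect_equal(
      sub$g_per_animal[sub$day == 7],
      mean(sub$g_per_animal[sub$day %in% c(5, 6, 8, 9)])
    )
  }

  # without injection nothing is flagged or substituted
  clean <- substitute_missing(run_daily(tr))
  expect_equal(sum(clean$substituted), 0)
  expect_true(all(clean$n_valid >= 4))

  expect_error(inject_analyzer_failure(tr, "CH4", day = 10), "outside")
})

test_that("trial tables round-trip through the CSV/YAML interchange format", {
  tr <- simulate_trial(small_cfg(days = 1))
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  expect_true(all(file.exists(file.path(
    dir, c("readings.csv", "fans.csv", "events.csv", "inventory.csv",
      "bw.csv", "feed.csv", "carcass.csv", "config.yaml")
  ))))
  back <- read_trial(dir)
  expect_equal(back$config$doses, tr$config$doses)
  expect_equal(back$config$seed, tr$config$seed)
  expect_equal(back$config$effects$base_rate, tr$config$effects$base_rate)
  expect_equal(nrow(back$readings), nrow(tr$readings))
  expect_equal(back$readings$value, tr$readings$value, tolerance = 1e-12)
  expect_equal(back$inventory$headcount, tr$inventory$headcount)
})
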