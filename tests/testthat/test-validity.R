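# A hand-built reading stream: one cycle, one gas, chosen sources/periods.
build_readings <- function(n_periods = 4, source = "CPE1", gas = "NH3",
                           value = 100) {
  ts <- seq(0, n_periods * 900 - 15, by = 15)
  tibble::tibble(
    cycle = 1, timestamp = ts, source = source, gas = gas,
    value = value, unit = "ug/L", temp_c = 20, rh_pct = 50
  )
}

test_that("door events exclude a window from 5 min before to 15 min after", {
  rd <- build_readings(n_periods = 8)
  # bunk flap open 2 min starting at t = 1800 -> exclusion [1500, 3720]
  ev <- tibble::tibble(
    cycle = 1, cpe_id = "CPE1", kind = "bunk_flap",
    open_time = 1800, close_time = 1920
  )
  out <- mark_exclusions(rd, ev)
  excl_span <- range(out$timestamp[out$excluded])
  expect_equal(excl_span, c(1500, 2820))
  # 22 min of readings removed: (5 + 2 + 15) min * 4 readings/min
  expect_equal(sum(out$excluded), 22 * 4 + 1) # inclusive endpoints at cadence
})

test_that("small-door events and foreign enclosures exclude nothing", {
  rd <- build_readings()
  small <- tibble::tibble(
    cycle = 1, cpe_id = "CPE1", kind = "small_door",
    open_time = 100, close_time = 200
  )
  other <- tibble::tibble(
    cycle = 1, cpe_id = "CPE2", kind = "large_door",
    open_time = 100, close_time = 200
  )
  expect_equal(sum(mark_exclusions(rd, small)$excluded), 0)
  expect_equal(sum(mark_exclusions(rd, other)$excluded), 0)
  expect_equal(sum(mark_exclusions(rd, small[0, ])$excluded), 0)
  bad <- dplyr::mutate(small, kind = "window")
  expect_error(mark_exclusions(rd, bad), "unknown event kind")
})

test_that("exclusion marking is idempotent and unions overlapping windows", {
  rd <- build_readings(n_periods = 8)
  ev <- tibble::tibble(
    cycle = 1, cpe_id = "CPE1", kind = c("bunk_flap", "large_door"),
    open_time = c(1800, 2000), close_time = c(1900, 2100)
  )
  once <- mark_exclusions(rd, ev)
  twice <- mark_exclusions(once, ev)
  expect_identical(once$excluded, twice$excluded)
  # overlapping windows: union, not double counting
  expect_equal(
    sum(once$excluded),
    sum(once$timestamp >= 1500 & once$timestamp <= 3000)
  )
})

test_that("a period needs at least 4 min (16 readings) of clean data", {
  rd <- build_readings(n_periods = 1)
  p <- summarize_periods(rd)
  expect_true(p$is_valid)
  expect_equal(p$valid_minutes, 15)
  expect_equal(p$n_readings, 60)

  # 45 of 60 excluded leaves 3.75 min -> invalid
  rd$excluded <- c(rep(TRUE, 45), rep(FALSE, 15))
  expect_false(summarize_periods(rd)$is_valid)

  # exactly 16 clean readings -> valid (boundary inclusive)
  rd$excluded <- c(rep(TRUE, 44), rep(FALSE, 16))
  p <- summarize_periods(rd)
  expect_true(p$is_valid)
  expect_equal(p$valid_minutes, 4)
  expect_true(period_validity(16L))
  expect_false(period_validity(15L))
})

test_that("period summaries average only clean readings and keep the start day", {
  rd <- build_readings(n_periods = 1)
  rd$value <- seq_len(60)
  rd$excluded <- rd$value <= 20
  p <- summarize_periods(rd)
  expect_equal(p$mean_value, mean(21:60))
  expect_equal(p$day, 0)
  # a period late on day 0 belongs to day 0; the first of day 1 to day 1
  late <- build_readings(n_periods = 1)
  late$timestamp <- late$timestamp + 95 * 900
  expect_equal(summarize_periods(late)$day, 0)
  next_day <- build_readings(n_periods = 1)
  next_day$timestamp <- next_day$timestamp + 96 * 900
  expect_equal(summarize_periods(next_day)$day, 1)
})

test_that("neighbour-day substitution averages days d-2, d-1, d+1, d+2", {
  daily <- tibble::tibble(
    cycle = 1, cpe_id = "CPE1", gas = "CH4", day = 0:10,
    mean_flux = NA_real_, n_valid = 11L, headcount = 14,
    g_per_animal = c(1, 2, 3, 4, 5, 10, 12, NA, 14, 16, 9),
    substituted = FALSE
  )
  daily$n_valid[daily$day == 7] <- 2L
  out <- substitute_missing(daily)
  expect_equal(out$g_per_animal[out$day == 7], mean(c(10, 12, 14, 16)))
  expect_true(out$substituted[out$day == 7])
  expect_equal(sum(out$substituted), 1)

  # a failure at the boundary has no day -2 and must error
  daily2 <- daily
  daily2$n_valid <- 11L
  daily2$g_per_animal[1] <- NA
  daily2$n_valid[1] <- 0L
  expect_error(substitute_missing(daily2), "unrecoverable")

  # an invalid neighbour also blocks substitution
  daily3 <- daily
  daily3$n_valid[daily3$day == 8] <- 1L
  daily3$g_per_animal[daily3$day == 8] <- NA
  expect_error(substitute_missing(daily3), "unrecoverable")

  # nothing to substitute leaves the table untouched
  clean <- daily
  clean$n_valid <- 11L
  clean$g_per_animal[8] <- 13
  expect_identical(substitute_missing(clean)$substituted, rep(FALSE, 11))
})
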