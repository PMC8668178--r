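#' Effect model for the synthetic trial generator
#'
#' Phenomenological generating parameters for a dose-titration feeding trial
#' in ventilated pen enclosures. Defaults are the study conditions the
#' analysis assumes: four doses \{0, 1.38, 5.5, 22\} mg/kg DM of a
#' beta-adrenergic modulator fed to 14 cattle per enclosure for 91 d,
#' NH3 emission reduced multiplicatively at the treated doses, growth and
#' carcass responses of feedlot-typical magnitude, and noise components
#' (reading, day, pen, cycle) that reproduce pen-to-pen SEMs of the order
#' reported for such trials. All multiplicative noise terms are mean-one
#' lognormals, so expected emissions are available in closed form
#' ([expected_daily_emission()]).
#'
#' @param ... Named overrides of any default component.
#' @return List of class `effect_model`.
#' @export
effect_model <- function(...) {
  defaults <- list(
    # per-animal daily emission baselines, g/animal/d (N2O runs below ambient)
    base_rate = c(NH3 = 85.5, CH4 = 115, CO2 = 7912, H2S = 0.226, N2O = -0.30),
    # multiplicative dose effect on NH3 (control first, must be 1)
    nh3_dose_mult = c(1, 0.911, 0.881, 0.867),
    diurnal_amplitude = 0.3,
    diurnal_peak_hour = 14,
    reading_noise_cv = 0.10,
    day_cv = 0.08,
    pen_cv = 0.25,
    cycle_cv = 0.12,
    # ambient concentrations in each gas's native unit, AR(1) over periods
    ambient_mean = c(NH3 = 600, CH4 = 1.9, CO2 = 450, H2S = 2, N2O = 0.33),
    ambient_ar1 = 0.9,
    ambient_cv = 0.02,
    # fans
    fan_flow_start_mean = 55, fan_flow_start_sd = 2.5,
    fan_decay_range = c(0.82, 0.92),
    # climate
    temp_mean = 24, temp_amp = 6, temp_peak_hour = 15,
    rh_mean = 60, rh_amp = -15,
    # growth
    initial_bw_mean = c(steer = 475, heifer = 432), initial_bw_sd = 30,
    adg_base = 1.27,
    adg_dose_mult = c(1, 1.118, 1.094, 1.126),
    adg_pen_sd = 0.08, bw_meas_sd = 8,
    # intake
    dmi_base = 8.8, dmi_sex_add = c(steer = 0.25, heifer = -0.25),
    dmi_pen_sd = 0.5, dm_fraction = 0.765,
    orts_frac_range = c(0.01, 0.05),
    # carcass
    dressing = c(0.615, 0.624, 0.627, 0.628), dressing_sd = 0.010,
    fat_mean = c(1.28, 1.15, 1.24, 1.19), fat_sd = 0.30,
    fat_sex_add = c(steer = -0.085, heifer = 0.085),
    lm_mean = c(88.4, 94.8, 96.1, 96.8), lm_sd = 8,
    kph_mean = c(1.96, 1.99, 1.96, 1.61), kph_sd = 0.40,
    kph_sex_add = c(steer = -0.22, heifer = 0.22),
    marbling_mean = c(623, 573, 560, 562), marbling_sd = 80,
    maturity_mean = 168, maturity_sd = 12,
    wbsf_mean = c(2.48, 2.79, 2.92, 2.75), wbsf_core_sd = 0.45,
    # attrition and disturbance
    removal_hazard = 4e-4, headcount_floor = 10,
    bunk_flap_rate = 0.08, large_door_rate = 0.02, small_door_rate = 0.3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown effect_model components: ", paste(bad, collapse = ", ")))
  }
  defaults[names(over)] <- over
  em <- defaults
  if (em$nh3_dose_mult[1] != 1) {
    rlang::abort("dose effect at dose 0 must be exactly 1")
  }
  if (any(em$nh3_dose_mult[-1] > 1)) {
    rlang::abort("NH3 dose effects at positive doses must be <= 1 (reductions)")
  }
  structure(em, class = "effect_model")
}

#' Trial configuration
#'
#' Design constants of the simulated trial. Defaults are the standard study
#' conditions: three 91-d cycles of eight enclosures, one enclosure per
#' dose-by-sex combination per cycle, a continuous rotation over ambient
#' air plus the eight enclosures in 15-min sampling periods at a 15-s
#' analyzer cadence, with measurements ending 3 h before the final 0800
#' (0500 h of the last day).
#'
#' @param doses Dose levels (mg/kg DM), ascending, including 0.
#' @param sexes Sex labels.
#' @param n_cycles Number of cycles (blocks).
#' @param animals_per_cpe Cattle per enclosure at day 0.
#' @param days Treatment days per cycle.
#' @param gases Gases monitored.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @param effects An [effect_model()].
#' @param end_offset_hours Hours before the final 0800 at which measurement
#'   stops.
#' @return List of class `trial_config`.
#' @export
trial_config <- function(doses = c(0, 1.38, 5.5, 22.0),
                         sexes = c("steer", "heifer"),
                         n_cycles = 3, animals_per_cpe = 14, days = 91,
                         gases = c("NH3", "CH4", "CO2", "H2S", "N2O"),
                         seed = 1, effects = effect_model(),
                         end_offset_hours = 3) {
  if (is.unsorted(doses, strictly = TRUE)) {
    rlang::abort("doses must be strictly ascending")
  }
  if (doses[1] != 0) rlang::abort("dose 0 (control) must be included")
  if (length(effects$nh3_dose_mult) != length(doses)) {
    rlang::abort("effects$nh3_dose_mult must have one entry per dose")
  }
  if (!all(gases %in% gas_species()$gas)) rlang::abort("unknown gas in config")
  n_cpe <- length(doses) * length(sexes)
  structure(
    list(
      doses = doses, sexes = sexes, n_cycles = n_cycles, n_cpe = n_cpe,
      animals_per_cpe = animals_per_cpe, days = days, gases = gases,
      rotation = c("ambient", paste0("CPE", seq_len(n_cpe))),
      seed = seed, effects = effects, end_offset_hours = end_offset_hours
    ),
    class = "trial_config"
  )
}

#' Analytic mean daily per-animal emission under the effect model
#'
#' All noise components are mean-one lognormals and the diurnal factor
#' integrates to one over a day, so the expected per-animal daily emission
#' is simply `base_rate[gas] * dose multiplier`.
#'
#' @param effects An [effect_model()].
#' @param gas Gas name.
#' @param dose_index Position of the dose in the config's dose vector.
#' @return Expected g/animal/day.
#' @export
expected_daily_emission <- function(effects, gas, dose_index = 1) {
  mult <- if (gas == "NH3") effects$nh3_dose_mult[dose_index] else 1
  unname(effects$base_rate[gas] * mult)
}

# mean-one lognormal deviates with coefficient of variation cv
rlnorm1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# hour of day for a trial timestamp (t = 0 is 0800)
hour_of_day <- function(t) ((t + 8 * 3600) %% .SECONDS_PER_DAY) / 3600

diurnal_factor <- function(t, amplitude, peak_hour) {
  1 + amplitude * cos(2 * pi * (hour_of_day(t) - peak_hour) / 24)
}

#' Simulate a complete enclosure feeding trial
#'
#' Generates every input table the pipeline consumes: 15-s analyzer readings
#' on the continuous rotation, fan calibrations, enclosure climate, door
#' events, per-day animal inventory, interim body weights, feed deliveries
#' and orts, and per-animal carcass records — together with the generating
#' truth (per-day true emissions and the parameters), so parameter-recovery
#' tests need no external data.
#'
#' @param config A [trial_config()].
#' @param readings Generate the 15-s reading stream (`TRUE`) or only the
#'   day-level truth and husbandry tables (`FALSE`, much faster; useful when
#'   only the design-level structure is needed).
#' @return List of class `synthetic_trial` with elements `config`,
#'   `allocation`, `truth`, `readings`, `fans`, `climate`, `events`,
#'   `inventory`, `bw`, `feed`, `carcass`, `weigh_days`.
#' @export
simulate_trial <- function(config = trial_config(), readings = TRUE) {
  stopifnot(inherits(config, "trial_config"))
  em <- config$effects
  set.seed(config$seed)
  n_src <- length(config$rotation)
  t_end <- config$days * .SECONDS_PER_DAY - config$end_offset_hours * 3600
  weigh_days <- unique(c(
    intersect(c(0, 7, 14, 28, 56), 0:config$days), config$days
  ))

  # --- treatment allocation: one CPE per dose x sex per cycle -------------
  combos <- tidyr::expand_grid(dose = config$doses, sex = config$sexes)
  allocation <- purrr::map_dfr(seq_len(config$n_cycles), function(cy) {
    idx <- sample(nrow(combos))
    tibble::tibble(
      cycle = cy, cpe_id = paste0("CPE", seq_len(config$n_cpe)),
      dose = combos$dose[idx], sex = combos$sex[idx]
    )
  })

  # --- animals, removals, inventory, body weights -------------------------
  animals <- allocation %>%
    dplyr::group_by(.data$cycle, .data$cpe_id, .data$dose, .data$sex) %>%
    dplyr::reframe(animal_id = sprintf(
      "c%d_%s_a%02d", .data$cycle[1], .data$cpe_id[1],
      seq_len(config$animals_per_cpe)
    )) %>%
    dplyr::ungroup()
  n_animal <- nrow(animals)
  animals$bw0 <- em$initial_bw_mean[animals$sex] +
    stats::rnorm(n_animal, 0, em$initial_bw_sd)

  pen_key <- dplyr::distinct(allocation, .data$cycle, .data$cpe_id, .data$dose, .data$sex)
  pen_key$dose_index <- match(pen_key$dose, config$doses)
  pen_key$adg_pen <- em$adg_base * em$adg_dose_mult[pen_key$dose_index] +
    stats::rnorm(nrow(pen_key), 0, em$adg_pen_sd)
  animals <- dplyr::left_join(
    animals, pen_key[, c("cycle", "cpe_id", "dose_index", "adg_pen")],
    by = c("cycle", "cpe_id")
  )

  # removal day (Inf = stays); a per-day Bernoulli hazard with a hard pen floor
  draw <- matrix(
    stats::runif(n_animal * config$days) < em$removal_hazard,
    nrow = n_animal
  )
  animals$removal_day <- Inf
  for (p in seq_len(nrow(pen_key))) {
    rows <- which(animals$cycle == pen_key$cycle[p] &
      animals$cpe_id == pen_key$cpe_id[p])
    present <- length(rows)
    for (d in seq_len(config$days)) {
      for (r in rows) {
        if (is.infinite(animals$removal_day[r]) && draw[r, d] &&
          present > em$headcount_floor) {
          animals$removal_day[r] <- d - 1
          present <- present - 1
        }
      }
    }
  }

  # removed animals count through their removal day
  inventory <- animals %>%
    dplyr::group_by(.data$cycle, .data$cpe_id) %>%
    dplyr::reframe({
      rd <- .data$removal_day
      tibble::tibble(
        day = 0:(config$days - 1),
        headcount = vapply(
          0:(config$days - 1), function(d) sum(rd >= d), integer(1)
        )
      )
    }) %>%
    dplyr::ungroup()

  bw <- tidyr::expand_grid(
    animals[, c("cycle", "cpe_id", "animal_id", "sex", "bw0", "adg_pen", "removal_day")],
    day = weigh_days
  ) %>%
    dplyr::filter(.data$day <= .data$removal_day | .data$day == 0) %>%
    dplyr::mutate(
      bw_kg = .data$bw0 + .data$adg_pen * .data$day +
        stats::rnorm(dplyr::n(), 0, em$bw_meas_sd)
    ) %>%
    dplyr::select("cycle", "cpe_id", "animal_id", "sex", "day", "bw_kg")

  # --- truth: per-day true emission rates --------------------------------
  gas_mult <- function(gas, dose_index) {
    ifelse(gas == "NH3", em$nh3_dose_mult[dose_index], 1)
  }
  truth <- tidyr::expand_grid(
    pen_key[, c("cycle", "cpe_id", "dose", "sex", "dose_index")],
    gas = config$gases, day = 0:(config$days - 1)
  )
  cyc_eff <- array(
    rlnorm1(config$n_cycles * length(config$gases), em$cycle_cv),
    dim = c(config$n_cycles, length(config$gases)),
    dimnames = list(NULL, config$gases)
  )
  pen_eff_tbl <- tidyr::expand_grid(
    pen_key[, c("cycle", "cpe_id")], gas = config$gases
  ) %>%
    dplyr::mutate(pen_eff = rlnorm1(dplyr::n(), em$pen_cv))
  truth <- truth %>%
    dplyr::left_join(pen_eff_tbl, by = c("cycle", "cpe_id", "gas")) %>%
    dplyr::mutate(
      rate_g_animal_day = unname(em$base_rate[.data$gas]) *
        gas_mult(.data$gas, .data$dose_index) *
        cyc_eff[cbind(.data$cycle, match(.data$gas, config$gases))] *
        .data$pen_eff *
        rlnorm1(dplyr::n(), em$day_cv)
    ) %>%
    dplyr::left_join(inventory, by = c("cycle", "cpe_id", "day"))

  # --- fans ---------------------------------------------------------------
  fans <- tidyr::expand_grid(
    pen_key[, c("cycle", "cpe_id")], fan = 1:2
  ) %>%
    dplyr::mutate(
      fan_id = paste0(.data$cpe_id, "_fan", .data$fan),
      t0 = 0, t1 = t_end,
      flow_start = stats::rnorm(dplyr::n(), em$fan_flow_start_mean, em$fan_flow_start_sd),
      flow_end = .data$flow_start *
        stats::runif(dplyr::n(), em$fan_decay_range[1], em$fan_decay_range[2])
    ) %>%
    dplyr::select("cycle", "cpe_id", "fan_id", "t0", "t1", "flow_start", "flow_end")

  # --- door events ---------------------------------------------------------
  events <- purrr::map_dfr(seq_len(config$n_cycles), function(cy) {
    purrr::map_dfr(paste0("CPE", seq_len(config$n_cpe)), function(cpe) {
      rates <- c(
        bunk_flap = em$bunk_flap_rate, large_door = em$large_door_rate,
        small_door = em$small_door_rate
      )
      purrr::map_dfr(names(rates), function(kind) {
        n_ev <- stats::rbinom(1, config$days, min(rates[[kind]], 1))
        if (n_ev == 0) return(NULL)
        open <- sort(stats::runif(n_ev, 0, t_end - 360))
        tibble::tibble(
          cycle = cy, cpe_id = cpe, kind = kind,
          open_time = open,
          close_time = open + stats::runif(n_ev, 60, 300)
        )
      })
    })
  })

  if (nrow(events) == 0) {
    events <- tibble::tibble(
      cycle = integer(), cpe_id = character(), kind = character(),
      open_time = double(), close_time = double()
    )
  }

  # --- climate (period resolution) ----------------------------------------
  n_periods <- ceiling(t_end / .SECONDS_PER_PERIOD)
  climate <- purrr::map_dfr(seq_len(config$n_cycles), function(cy) {
    tm <- (seq_len(n_periods) - 0.5) * .SECONDS_PER_PERIOD
    tibble::tibble(
      cycle = cy, period = seq_len(n_periods) - 1, t_mid = tm,
      temp_c = em$temp_mean +
        em$temp_amp * cos(2 * pi * (hour_of_day(tm) - em$temp_peak_hour) / 24),
      rh_pct = pmin(95, pmax(20, em$rh_mean +
        em$rh_amp * cos(2 * pi * (hour_of_day(tm) - em$temp_peak_hour) / 24)))
    )
  })

  # --- feed ----------------------------------------------------------------
  pen_dmi <- pen_key %>%
    dplyr::mutate(dmi_true = em$dmi_base + em$dmi_sex_add[.data$sex] +
      stats::rnorm(dplyr::n(), 0, em$dmi_pen_sd))
  feed <- inventory %>%
    dplyr::left_join(
      pen_dmi[, c("cycle", "cpe_id", "dmi_true")],
      by = c("cycle", "cpe_id")
    ) %>%
    dplyr::mutate(
      consumed = .data$headcount * .data$dmi_true / em$dm_fraction,
      of = stats::runif(dplyr::n(), em$orts_frac_range[1], em$orts_frac_range[2]),
      delivered_asfed_kg = .data$consumed * (1 + .data$of),
      orts_daily = .data$consumed * .data$of
    )
  feed <- feed %>%
    dplyr::group_by(.data$cycle, .data$cpe_id) %>%
    dplyr::mutate(orts_asfed_kg = ifelse(
      .data$day == max(.data$day), sum(.data$orts_daily), 0
    )) %>%
    dplyr::ungroup() %>%
    dplyr::select("cycle", "cpe_id", "day", "delivered_asfed_kg", "orts_asfed_kg")

  # --- carcass -------------------------------------------------------------
  finishers <- animals %>% dplyr::filter(is.infinite(.data$removal_day))
  di <- finishers$dose_index
  n_f <- nrow(finishers)
  carcass <- finishers %>%
    dplyr::mutate(
      final_bw = .data$bw0 + .data$adg_pen * config$days,
      hcw_kg = em$dressing[di] * .data$final_bw *
        (1 + stats::rnorm(n_f, 0, em$dressing_sd)),
      adj_fat_cm = pmax(0.2, em$fat_mean[di] + em$fat_sex_add[.data$sex] +
        stats::rnorm(n_f, 0, em$fat_sd)),
      lm_cm2 = pmax(40, em$lm_mean[di] + stats::rnorm(n_f, 0, em$lm_sd)),
      kph_pct = pmax(0.5, em$kph_mean[di] + em$kph_sex_add[.data$sex] +
        stats::rnorm(n_f, 0, em$kph_sd)),
      marbling = pmax(200, em$marbling_mean[di] + stats::rnorm(n_f, 0, em$marbling_sd)),
      maturity = pmax(100, pmin(299, em$maturity_mean +
        stats::rnorm(n_f, 0, em$maturity_sd)))
    ) %>%
    dplyr::select(
      "cycle", "cpe_id", "animal_id", "sex", "hcw_kg", "adj_fat_cm",
      "lm_cm2", "kph_pct", "marbling", "maturity"
    ) %>%
    dplyr::mutate(
      yg_continuous = yield_grade(.data$adj_fat_cm, .data$kph_pct, .data$hcw_kg, .data$lm_cm2),
      yg_class = yield_grade_class(.data$yg_continuous),
      quality = quality_class(.data$marbling, .data$maturity)
    )
  # shear force on three striploins per pen
  carcass <- carcass %>%
    dplyr::group_by(.data$cycle, .data$cpe_id) %>%
    dplyr::mutate(wbsf_sampled = dplyr::row_number() %in%
      sample(dplyr::n(), min(3, dplyr::n()))) %>%
    dplyr::ungroup() %>%
    dplyr::left_join(pen_key[, c("cycle", "cpe_id", "dose_index")], by = c("cycle", "cpe_id"))
  carcass$wbsf_kg <- ifelse(
    carcass$wbsf_sampled,
    purrr::map_dbl(seq_len(nrow(carcass)), function(i) {
      wbsf_mean(em$wbsf_mean[carcass$dose_index[i]] +
        stats::rnorm(6, 0, em$wbsf_core_sd))
    }),
    NA_real_
  )
  carcass <- dplyr::select(carcass, -"wbsf_sampled", -"dose_index")

  # --- analyzer readings ----------------------------------------------------
  readings_tbl <- NULL
  if (readings) {
    readings_tbl <- simulate_readings(
      config, allocation, truth, inventory, fans, climate, t_end
    )
  }

  structure(
    list(
      config = config, allocation = allocation,
      truth = list(
        effects = em,
        daily = dplyr::select(
          truth, "cycle", "cpe_id", "dose", "sex", "gas", "day",
          "rate_g_animal_day", "headcount"
        )
      ),
      readings = readings_tbl, fans = fans, climate = climate,
      events = events, inventory = inventory, bw = bw, feed = feed,
      carcass = carcass, weigh_days = weigh_days
    ),
    class = "synthetic_trial"
  )
}

# The 15-s reading stream for all cycles: each gas analyzer records the
# currently sampled source; net enclosure concentrations are obtained by
# inverting the flux equation at the instantaneous true flux, airflow and
# temperature, and adding the AR(1) ambient baseline.
simulate_readings <- function(config, allocation, truth, inventory, fans,
                              climate, t_end) {
  em <- config$effects
  n_src <- length(config$rotation)
  ticks <- seq(0, t_end - .SECONDS_PER_READING, by = .SECONDS_PER_READING)
  period <- floor(ticks / .SECONDS_PER_PERIOD)
  src_idx <- (period %% n_src) + 1
  day <- floor(ticks / .SECONDS_PER_DAY)
  n_periods <- max(period) + 1
  diurnal <- diurnal_factor(ticks, em$diurnal_amplitude, em$diurnal_peak_hour)
  sp <- gas_species()

  purrr::map_dfr(seq_len(config$n_cycles), function(cy) {
    cl <- climate[climate$cycle == cy, ]
    temp_tick <- cl$temp_c[period + 1]
    rh_tick <- cl$rh_pct[period + 1]
    # per-CPE airflow is linear in t: precompute intercept/slope per source
    af0 <- af1 <- numeric(n_src)
    for (s in 2:n_src) {
      f <- fans[fans$cycle == cy & fans$cpe_id == config$rotation[s], ]
      slope <- sum((f$flow_end - f$flow_start) / (f$t1 - f$t0))
      af0[s] <- sum(f$flow_start)
      af1[s] <- slope
    }
    airflow_tick <- af0[src_idx] + af1[src_idx] * ticks

    rate_cy <- truth[truth$cycle == cy, ]
    purrr::map_dfr(config$gases, function(g) {
      # ambient AR(1) at period resolution
      mu <- em$ambient_mean[[g]]
      innov_sd <- mu * em$ambient_cv * sqrt(1 - em$ambient_ar1^2)
      dev <- as.numeric(stats::filter(
        stats::rnorm(n_periods, 0, innov_sd),
        em$ambient_ar1, method = "recursive",
        init = stats::rnorm(1, 0, mu * em$ambient_cv)
      ))
      amb_tick <- mu + dev[period + 1]

      r <- rate_cy[rate_cy$gas == g, ]
      rate_mat <- matrix(NA_real_, nrow = n_src, ncol = config$days)
      head_mat <- matrix(NA_real_, nrow = n_src, ncol = config$days)
      si <- match(r$cpe_id, config$rotation)
      rate_mat[cbind(si, r$day + 1)] <- r$rate_g_animal_day
      head_mat[cbind(si, r$day + 1)] <- r$headcount

      value <- amb_tick
      is_cpe <- src_idx > 1
      flux_true <- rate_mat[cbind(src_idx[is_cpe], day[is_cpe] + 1)] *
        head_mat[cbind(src_idx[is_cpe], day[is_cpe] + 1)] / .MINUTES_PER_DAY *
        diurnal[is_cpe]
      net <- concentration_for_flux(
        flux_true, g, airflow_tick[is_cpe], temp_tick[is_cpe]
      )
      noise <- 1 + stats::rnorm(sum(is_cpe), 0, em$reading_noise_cv)
      value[is_cpe] <- amb_tick[is_cpe] + net * noise

      tibble::tibble(
        cycle = cy, timestamp = ticks,
        source = config$rotation[src_idx], gas = g,
        value = value, unit = sp$unit[sp$gas == g],
        temp_c = temp_tick, rh_pct = rh_tick
      )
    })
  })
}

#' Inject an analyzer failure into a simulated trial
#'
#' Marks every reading of one gas on one 0800-anchored day of a cycle as
#' excluded (the single analyzer for that gas is down), leaving fewer than
#' four valid sampling periods for that gas-day in every enclosure, so the
#' validity rules must route the day to neighbour-day substitution.
#'
#' @param trial A [simulate_trial()] result with readings.
#' @param gas Gas whose analyzer fails.
#' @param day Day index of the failure (0-based).
#' @param cycle Affected cycle.
#' @return The trial with `readings$excluded` set and a `failures` record.
#' @export
inject_analyzer_failure <- function(trial, gas, day, cycle = 1) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (is.null(trial$readings)) rlang::abort("trial was simulated without readings")
  if (day < 0 || day >= trial$config$days) {
    rlang::abort("failure day outside the trial window")
  }
  if (!"excluded" %in% names(trial$readings)) trial$readings$excluded <- FALSE
  hit <- trial$readings$cycle == cycle & trial$readings$gas == gas &
    floor(trial$readings$timestamp / .SECONDS_PER_DAY) == day
  trial$readings$excluded <- trial$readings$excluded | hit
  trial$failures <- dplyr::bind_rows(
    trial$failures, tibble::tibble(cycle = cycle, gas = gas, day = day)
  )
  trial
}

#' Simulate a pen-level response table for the RCBD design
#'
#' Direct generator of a balanced design table (one pen per cycle per
#' dose-by-sex cell) with additive cycle effects and iid pen residuals —
#' the fast path for statistical power, coverage and type-I error studies
#' that do not need the reading-level machinery.
#'
#' @param dose_means Named or ordered vector of true means, one per dose.
#' @param sd_resid Pen residual SD.
#' @param sd_cycle Cycle (block) effect SD.
#' @param sex_effect Additive effect of the second sex level.
#' @param doses Dose grid.
#' @param sexes Sex labels.
#' @param n_cycles Number of cycles.
#' @return Tibble with `cycle`, `dose`, `sex`, `value`.
#' @export
simulate_pen_table <- function(dose_means, sd_resid, sd_cycle = 0,
                               sex_effect = 0,
                               doses = c(0, 1.38, 5.5, 22.0),
                               sexes = c("steer", "heifer"), n_cycles = 3) {
  stopifnot(length(dose_means) == length(doses))
  tab <- tidyr::expand_grid(
    cycle = seq_len(n_cycles), dose = doses, sex = sexes
  )
  cyc <- stats::rnorm(n_cycles, 0, sd_cycle)
  tab$value <- dose_means[match(tab$dose, doses)] +
    cyc[tab$cycle] +
    ifelse(tab$sex == sexes[length(sexes)], sex_effect, 0) +
    stats::rnorm(nrow(tab), 0, sd_resid)
  tab
}
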