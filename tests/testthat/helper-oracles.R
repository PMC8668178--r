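# Independent oracles used across the suite. Each re-derives a quantity by a
# different route than the implementation under test.

# Dimensional-analysis flux oracle: unit conversion spelt out step by step.
oracle_flux <- function(net_conc, gas, airflow_m3_min, temp_c) {
  mw <- c(NH3 = 17.03, CH4 = 16.04, CO2 = 44.01, H2S = 34.08, N2O = 44.01)[[gas]]
  per_litre_to_gram <- if (gas %in% c("NH3", "H2S")) 1e-9 else 1e-6
  litres_per_min <- airflow_m3_min * 1000
  molar_volume_at_t <- 22.4 * (temp_c + 273.15) / 273.15 # L/mol
  mol_per_min <- net_conc * litres_per_min / molar_volume_at_t
  mol_per_min * mw * per_litre_to_gram
}

# Hand linear interpolation for a single fan.
oracle_fan_flow <- function(t0, t1, f0, f1, t) {
  f0 + (f1 - f0) * (t - t0) / (t1 - t0)
}

# Brute-force design-matrix least-squares oracle for the balanced RCBD:
# sequential projections give the sums of squares; LSMeans and contrasts come
# from the coefficient vector with explicit (X'X)^{-1} standard errors.
oracle_rcbd <- function(data) {
  data <- as.data.frame(data)
  data$cycle <- factor(data$cycle)
  data$dosef <- factor(data$dose)
  data$sexf <- factor(data$sex)
  y <- data$value
  n <- length(y)

  forms <- list(
    ~1,
    ~cycle,
    ~ cycle + dosef,
    ~ cycle + dosef + sexf,
    ~ cycle + dosef * sexf
  )
  fitted_norm2 <- vapply(forms, function(f) {
    X <- stats::model.matrix(f, data)
    q <- qr(X)
    sum(qr.fitted(q, y)^2)
  }, numeric(1))
  ss <- diff(fitted_norm2)
  X <- stats::model.matrix(forms[[5]], data)
  q <- qr(X)
  fitted <- qr.fitted(q, y)
  ss_resid <- sum((y - fitted)^2)
  df_resid <- n - ncol(X)
  mse <- ss_resid / df_resid

  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, y)
  doses <- sort(unique(data$dose))
  # LSMean of a dose: average model prediction over the sex x cycle grid
  lvec <- function(d) {
    grid <- expand.grid(
      cycle = levels(data$cycle), sexf = levels(data$sexf),
      dosef = factor(as.character(d), levels = levels(data$dosef))
    )
    colMeans(stats::model.matrix(forms[[5]], grid))
  }
  lsm <- vapply(doses, function(d) sum(lvec(d) * beta), numeric(1))
  contrast <- vapply(doses[-1], function(d) {
    l <- lvec(d) - lvec(doses[1])
    est <- sum(l * beta)
    se <- sqrt(mse * drop(t(l) %*% xtx_inv %*% l))
    tt <- est / se
    c(est, se, 2 * stats::pt(-abs(tt), df_resid))
  }, numeric(3))

  list(
    ss = stats::setNames(c(ss, ss_resid),
      c("cycle", "dose", "sex", "dose:sex", "residual")),
    mse = mse, df_resid = df_resid,
    f = ss / c(
      length(levels(data$cycle)) - 1, length(doses) - 1,
      length(levels(data$sexf)) - 1,
      (length(doses) - 1) * (length(levels(data$sexf)) - 1)
    ) / mse,
    lsmeans = stats::setNames(lsm, doses),
    contrast_est = contrast[1, ], contrast_se = contrast[2, ],
    contrast_p = contrast[3, ]
  )
}

# Exact conditional p for a 2 x k table by full enumeration of tables with
# the observed margins under the multivariate hypergeometric.
oracle_fisher_2xk <- function(tab) {
  tab <- as.matrix(tab)
  cm <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  rows <- expand.grid(lapply(cm, function(cj) 0:cj))
  rows <- rows[rowSums(rows) == r1, , drop = FALSE]
  logp <- apply(rows, 1, function(a) {
    sum(lchoose(cm, unlist(a))) - lchoose(n, r1)
  })
  p_obs <- sum(lchoose(cm, tab[1, ])) - lchoose(n, r1)
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# Shared small synthetic-trial configs -------------------------------------

# fully deterministic generator: every stochastic amplitude silenced
noiseless_effects <- function(...) {
  effect_model(
    reading_noise_cv = 0, day_cv = 0, pen_cv = 0, cycle_cv = 0,
    diurnal_amplitude = 0, ambient_cv = 0,
    temp_amp = 0, rh_amp = 0, fan_decay_range = c(1, 1),
    fan_flow_start_sd = 0,
    removal_hazard = 0,
    bunk_flap_rate = 0, large_door_rate = 0, small_door_rate = 0,
    adg_pen_sd = 0, bw_meas_sd = 0, initial_bw_sd = 0, dmi_pen_sd = 0,
    dressing_sd = 0,
    ...
  )
}
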