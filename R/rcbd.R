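#' Randomized-complete-block dose-by-sex ANOVA
#'
#' Fits the trial's analysis model for a continuous pen-level outcome:
#' fixed dose, sex and dose-by-sex effects with cycle as the block stratum,
#' one enclosure per dose-by-sex cell per cycle. In this balanced design the
#' classical sums-of-squares decomposition gives treatment F-tests, least
#' squares means and control contrasts identical to the REML mixed model
#' with a random cycle, so the closed form is used. For the standard design
#' (3 cycles, 4 doses, 2 sexes) the degrees of freedom are 2/3/1/3 with 14
#' residual df.
#'
#' Planned contrasts compare each non-control dose with the control
#' (smallest dose, which must be 0) in a pairwise fashion with no
#' multiplicity adjustment, on the residual df; the pooled-over-sex contrast
#' standard error is `sqrt(2 * MSE / (blocks * sexes))`.
#'
#' @param data Data frame with columns `cycle`, `dose` (numeric, includes 0),
#'   `sex`, and the response.
#' @param response Name of the response column (string).
#' @return An object of class `rcbd_fit`: a list with `anova` (term table),
#'   `lsmeans` (dose, sex and cell means with SEM), `contrasts` (pooled
#'   dose-vs-control), `contrasts_within_sex`, `mse`, `df_resid`, `gate`
#'   (see [interaction_gate()]).
#' @export
rcbd_fit <- function(data, response = "value") {
  stopifnot(all(c("cycle", "dose", "sex", response) %in% names(data)))
  y <- data[[response]]
  if (anyNA(y)) rlang::abort("response contains missing values")
  cyc <- as.character(data$cycle)
  dose <- data$dose
  sex <- as.character(data$sex)

  doses <- sort(unique(dose))
  sexes <- sort(unique(sex))
  cycles <- sort(unique(cyc))
  b <- length(cycles); d <- length(doses); s <- length(sexes)
  counts <- table(cyc, dose, sex)
  if (any(counts != 1)) {
    rlang::abort("design must be balanced: exactly one pen per cycle x dose x sex")
  }
  if (doses[1] != 0) rlang::abort("control dose 0 must be present")
  n <- length(y)

  gm <- mean(y)
  m_cyc <- tapply(y, cyc, mean)
  m_dose <- tapply(y, dose, mean)
  m_sex <- tapply(y, sex, mean)
  m_cell <- tapply(y, list(dose, sex), mean)

  ss_total <- sum((y - gm)^2)
  ss_cyc <- d * s * sum((m_cyc - gm)^2)
  ss_dose <- b * s * sum((m_dose - gm)^2)
  ss_sex <- b * d * sum((m_sex - gm)^2)
  int_dev <- sweep(sweep(m_cell, 1, m_dose - gm), 2, m_sex - gm) - gm
  ss_int <- b * sum(int_dev^2)
  ss_resid <- ss_total - ss_cyc - ss_dose - ss_sex - ss_int

  df <- c(
    cycle = b - 1, dose = d - 1, sex = s - 1,
    `dose:sex` = (d - 1) * (s - 1)
  )
  df_resid <- (n - 1) - sum(df)
  mse <- ss_resid / df_resid
  ss <- c(ss_cyc, ss_dose, ss_sex, ss_int)
  ms <- ss / df
  fstat <- ms / mse
  pval <- stats::pf(fstat, df, df_resid, lower.tail = FALSE)

  anova_tbl <- tibble::tibble(
    term = c(names(df), "residual"),
    df = c(unname(df), df_resid),
    sumsq = unname(c(ss, ss_resid)),
    meansq = unname(c(ms, mse)),
    statistic = c(unname(fstat), NA),
    p.value = c(unname(pval), NA)
  )

  sem_dose <- sqrt(mse / (b * s))
  sem_sex <- sqrt(mse / (b * d))
  sem_cell <- sqrt(mse / b)
  lsmeans <- dplyr::bind_rows(
    tibble::tibble(
      level = "dose", dose = doses, sex = NA_character_,
      lsmean = as.numeric(m_dose[as.character(doses)]), sem = sem_dose
    ),
    tibble::tibble(
      level = "sex", dose = NA_real_, sex = sexes,
      lsmean = as.numeric(m_sex[sexes]), sem = sem_sex
    ),
    tidyr::expand_grid(dose = doses, sex = sexes) %>%
      dplyr::mutate(
        level = "dose:sex",
        lsmean = purrr::map2_dbl(
          .data$dose, .data$sex,
          ~ m_cell[as.character(.x), .y]
        ),
        sem = sem_cell
      ) %>%
      dplyr::select("level", "dose", "sex", "lsmean", "sem")
  )

  ctr <- function(est, se) {
    tstat <- est / se
    tibble::tibble(
      estimate = est, std.error = se, statistic = tstat,
      p.value = 2 * stats::pt(-abs(tstat), df_resid)
    )
  }
  pooled <- tibble::tibble(dose = doses[-1]) %>%
    dplyr::bind_cols(ctr(
      as.numeric(m_dose[as.character(doses[-1])]) - m_dose[["0"]],
      sqrt(2 * mse / (b * s))
    ))
  within <- tidyr::expand_grid(sex = sexes, dose = doses[-1])
  within <- dplyr::bind_cols(within, ctr(
    purrr::map2_dbl(
      within$dose, within$sex,
      ~ m_cell[as.character(.x), .y] - m_cell["0", .y]
    ),
    sqrt(2 * mse / b)
  ))

  fit <- structure(
    list(
      response = response,
      n = n, blocks = b, doses = doses, sexes = sexes,
      anova = anova_tbl, lsmeans = lsmeans,
      contrasts = pooled, contrasts_within_sex = within,
      mse = mse, df_resid = df_resid
    ),
    class = "rcbd_fit"
  )
  fit$gate <- interaction_gate(fit)
  fit
}

#' Interaction gate: pooled or within-sex reporting
#'
#' If the dose-by-sex interaction is not significant (p > 0.05) the main
#' effect of dose pooled across sexes is evaluated; a significant
#' interaction (p <= 0.05, ties inclusive) routes reporting to within-sex
#' control contrasts.
#'
#' @param fit An [rcbd_fit()] object.
#' @return `"pooled"` or `"within_sex"`.
#' @export
interaction_gate <- function(fit) {
  p_int <- fit$anova$p.value[fit$anova$term == "dose:sex"]
  if (is.na(p_int)) return("pooled") # single-sex designs have no interaction
  if (p_int <= 0.05) "within_sex" else "pooled"
}

#' Significance label at the trial's reporting conventions
#'
#' @param p Numeric vector of p-values.
#' @return `"significant"` (p <= 0.05), `"tendency"` (0.05 < p <= 0.10) or
#'   `"ns"`.
#' @export
significance_label <- function(p) {
  dplyr::case_when(
    p <= 0.05 ~ "significant",
    p <= 0.10 ~ "tendency",
    TRUE ~ "ns"
  )
}

#' Control contrasts selected by the interaction gate
#'
#' @param fit An [rcbd_fit()] object.
#' @return The pooled dose-vs-control contrasts when the gate passes, the
#'   within-sex contrasts otherwise, with significance labels.
#' @export
contrasts_vs_control <- function(fit) {
  tbl <- if (fit$gate == "pooled") fit$contrasts else fit$contrasts_within_sex
  dplyr::mutate(tbl, label = significance_label(.data$p.value))
}

#' @export
print.rcbd_fit <- function(x, ...) {
  cat(sprintf(
    "RCBD fit of '%s' (%d pens: %d cycles x %d doses x %d sexes)\n",
    x$response, x$n, x$blocks, length(x$doses), length(x$sexes)
  ))
  print(as.data.frame(x$anova), digits = 4, row.names = FALSE)
  cat(sprintf("interaction gate: %s\n", x$gate))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an RCBD fit
#'
#' @param x An [rcbd_fit()] object.
#' @param ... Unused.
#' @return The ANOVA term table as a tibble.
#' @method tidy rcbd_fit
#' @export
tidy.rcbd_fit <- function(x, ...) x$anova

#' One-row summary of an RCBD fit
#'
#' @param x An [rcbd_fit()] object.
#' @param ... Unused.
#' @return Tibble with dose/sex/interaction p-values, MSE, residual df, SEM
#'   of a dose mean and the gate decision.
#' @method glance rcbd_fit
#' @export
glance.rcbd_fit <- function(x, ...) {
  p <- function(term) x$anova$p.value[x$anova$term == term]
  tibble::tibble(
    dose.p.value = p("dose"), sex.p.value = p("sex"),
    interaction.p.value = p("dose:sex"),
    mse = x$mse, df.residual = x$df_resid,
    sem = sqrt(x$mse / (x$blocks * length(x$sexes))),
    gate = x$gate
  )
}

#' Fisher's exact test for a 2-by-k frequency table
#'
#' Exact conditional test with fixed margins, as used for sparse categorical
#' outcomes (mortality, rare yield/quality grades) where the binomial mixed
#' model cannot converge: the two-sided p-value sums the probabilities of
#' all tables as or less probable than the observed one.
#'
#' @param counts Non-negative integer matrix with 2 rows (e.g. control vs
#'   treated) and k columns (categories).
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2xk(matrix(c(5, 0, 0, 5), nrow = 2)) # 2/252
fisher_exact_2xk <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("counts must be non-negative integers")
  }
  if (sum(counts) == 0) rlang::abort("all-zero table")
  stats::fisher.test(counts)$p.value
}

#' Binomial category analysis with control contrasts
#'
#' Pen-level category counts (e.g. carcasses in a yield-grade class) are
#' analysed with a binomial logit model containing dose, sex, dose-by-sex
#' and cycle as a fixed block (the fixed-block approximation to the
#' random-cycle GLMM), with Wald contrasts of each dose against control on
#' the logit scale. When the data are too sparse for the model — any dose
#' arm with zero (or saturated) counts, or a non-converged/separated fit —
#' the analysis falls back to [fisher_exact_2xk()] comparing control with
#' the pooled treated arms.
#'
#' @param data Pen-level counts: columns `cycle`, `dose`, `sex`,
#'   `successes`, `trials`.
#' @return List of class `binomial_fit`: `method` (`"glm"` or
#'   `"fisher_fallback"`), `probs` (per-dose estimated probability),
#'   `contrasts` (vs control; for the fallback a single pooled comparison),
#'   and `model` (the glm, when fitted).
#' @export
binomial_category_fit <- function(data) {
  stopifnot(all(c("cycle", "dose", "sex", "successes", "trials") %in% names(data)))
  if (any(data$successes < 0 | data$successes > data$trials)) {
    rlang::abort("successes must lie in [0, trials]")
  }
  arm <- data %>%
    dplyr::group_by(.data$dose) %>%
    dplyr::summarise(
      k = sum(.data$successes), n = sum(.data$trials), .groups = "drop"
    )
  sparse <- any(arm$k == 0) || any(arm$k == arm$n)

  fallback <- function() {
    con <- arm[arm$dose == 0, ]
    trt <- arm[arm$dose != 0, ]
    tab <- rbind(
      c(con$k, con$n - con$k),
      c(sum(trt$k), sum(trt$n) - sum(trt$k))
    )
    structure(
      list(
        method = "fisher_fallback",
        probs = dplyr::mutate(arm, prob = .data$k / .data$n),
        contrasts = tibble::tibble(
          comparison = "control vs pooled treated",
          p.value = fisher_exact_2xk(tab)
        ),
        model = NULL
      ),
      class = "binomial_fit"
    )
  }
  if (sparse) return(fallback())

  dat <- dplyr::mutate(data,
    dose = factor(.data$dose), cycle = factor(.data$cycle),
    sex = factor(.data$sex)
  )
  fit <- tryCatch(
    stats::glm(
      cbind(successes, trials - successes) ~ cycle + dose * sex,
      family = stats::binomial(), data = dat
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || !fit$converged) return(fallback())

  emm <- emmeans::emmeans(fit, "dose")
  cons <- as.data.frame(emmeans::contrast(emm, "trt.vs.ctrl", adjust = "none"))
  probs <- as.data.frame(emmeans::regrid(emm, "response"))
  structure(
    list(
      method = "glm",
      probs = tibble::tibble(
        dose = as.numeric(as.character(probs$dose)),
        prob = probs$prob, std.error = probs$SE
      ),
      contrasts = tibble::tibble(
        comparison = cons$contrast,
        estimate = cons$estimate, std.error = cons$SE,
        p.value = cons$p.value
      ),
      model = fit
    ),
    class = "binomial_fit"
  )
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat(sprintf("binomial category fit (%s)\n", x$method))
  print(as.data.frame(x$probs), digits = 3, row.names = FALSE)
  print(as.data.frame(x$contrasts), digits = 3, row.names = FALSE)
  invisible(x)
}
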