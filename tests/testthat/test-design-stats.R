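test_that("degenerate designs behave as the closed form predicts", {
  # all responses equal: every F is 0 (or NaN-free) and p = 1
  tab <- simulate_pen_table(rep(5, 4), sd_resid = 0)
  tab$value <- 5
  fit <- rcbd_fit(tab)
  expect_equal(fit$anova$sumsq, rep(0, 5), tolerance = 1e-20)
  ls <- fit$lsmeans[fit$lsmeans$level == "dose", ]
  expect_equal(ls$lsmean, rep(5, 4))

  # zero residual variance with distinct dose means: contrast p -> 0,
  # LSMeans equal the cell means exactly
  tab2 <- simulate_pen_table(c(10, 8, 6, 4), sd_resid = 0)
  fit2 <- rcbd_fit(tab2)
  ls2 <- fit2$lsmeans[fit2$lsmeans$level == "dose", ]
  expect_equal(ls2$lsmean, c(10, 8, 6, 4))
  expect_true(all(fit2$contrasts$p.value < 1e-12))

  # unbalanced tables are rejected
  expect_error(rcbd_fit(tab2[-1, ]), "balanced")
  no_ctl <- dplyr::mutate(tab2, dose = dose + 1)
  expect_error(rcbd_fit(no_ctl), "control dose 0")
})

test_that("the RCBD engine agrees with the design-matrix least-squares oracle", {
  set.seed(101)
  for (i in 1:50) {
    tab <- simulate_pen_table(
      dose_means = rnorm(4, 20, 3), sd_resid = runif(1, 0.5, 3),
      sd_cycle = runif(1, 0, 2), sex_effect = rnorm(1)
    )
    fit <- rcbd_fit(tab)
    orc <- oracle_rcbd(tab)
    expect_equal(fit$anova$sumsq, unname(orc$ss), tolerance = 1e-10)
    expect_equal(
      fit$anova$statistic[1:4], unname(orc$f), tolerance = 1e-10
    )
    expect_equal(fit$mse, orc$mse, tolerance = 1e-10)
    expect_equal(fit$df_resid, orc$df_resid)
    ls <- fit$lsmeans[fit$lsmeans$level == "dose", ]
    expect_equal(ls$lsmean, unname(orc$lsmeans), tolerance = 1e-10)
    expect_equal(fit$contrasts$estimate, unname(orc$contrast_est), tolerance = 1e-10)
    expect_equal(fit$contrasts$std.error, unname(orc$contrast_se), tolerance = 1e-10)
    expect_equal(fit$contrasts$p.value, unname(orc$contrast_p), tolerance = 1e-10)
  }
})

test_that("the interaction gate routes by the p <= 0.05 boundary convention", {
  fake_gate <- function(p_int) {
    fit <- structure(
      list(anova = tibble::tibble(term = "dose:sex", p.value = p_int)),
      class = "rcbd_fit"
    )
    interaction_gate(fit)
  }
  expect_equal(fake_gate(0.28), "pooled")
  expect_equal(fake_gate(0.04), "within_sex")
  expect_equal(fake_gate(0.05), "within_sex") # tie routes within sex

  expect_equal(significance_label(c(0.04, 0.05, 0.07, 0.10, 0.2)),
    c("significant", "significant", "tendency", "tendency", "ns"))

  # contrasts_vs_control follows the fitted gate
  set.seed(5)
  tab <- simulate_pen_table(c(20, 19, 18, 17), sd_resid = 1)
  fit <- rcbd_fit(tab)
  got <- contrasts_vs_control(fit)
  if (fit$gate == "pooled") {
    expect_equal(nrow(got), 3)
  } else {
    expect_equal(nrow(got), 6)
  }
})

test_that("Fisher's exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2xk(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_2xk(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
    tolerance = 1e-12)
  expect_equal(fisher_exact_2xk(matrix(c(4, 2, 6, 3), 2)), 1) # proportional rows
  set.seed(31)
  for (i in 1:15) {
    k <- sample(2:3, 1)
    tab <- matrix(rpois(2 * k, 3), nrow = 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2xk(tab), oracle_fisher_2xk(tab),
      tolerance = 1e-8)
  }
  expect_error(fisher_exact_2xk(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact_2xk(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("binomial category fits estimate probabilities and fall back when sparse", {
  pens <- tidyr::expand_grid(
    cycle = 1:3, dose = c(0, 1.38, 5.5, 22), sex = c("steer", "heifer")
  )
  # identical proportions everywhere: contrast estimates 0, p ~ 1
  eq <- dplyr::mutate(pens, successes = 5, trials = 14)
  fit_eq <- binomial_category_fit(eq)
  expect_equal(fit_eq$method, "glm")
  expect_true(all(abs(fit_eq$contrasts$estimate) < 1e-8))
  expect_true(all(fit_eq$contrasts$p.value > 0.999))
  expect_equal(fit_eq$probs$prob, rep(5 / 14, 4), tolerance = 1e-6)

  # a category absent from one arm triggers the exact-test fallback
  sp <- dplyr::mutate(eq, successes = ifelse(dose == 5.5, 0, successes))
  fit_sp <- binomial_category_fit(sp)
  expect_equal(fit_sp$method, "fisher_fallback")
  expect_true(fit_sp$contrasts$p.value <= 1)

  # a strong control-vs-treated difference is detected
  set.seed(77)
  strong <- dplyr::mutate(pens,
    trials = 14,
    successes = rbinom(dplyr::n(), 14, ifelse(dose == 0, 0.75, 0.2))
  )
  fit_strong <- binomial_category_fit(strong)
  expect_true(all(fit_strong$contrasts$p.value < 0.05))
})
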