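#' The five candidate dose-response mean functions
#'
#' The dose-titration analysis compares five competing linear and
#' linear-plateau shapes on the dose grid \{0, 1.38, 5.5, 22.0\} mg/kg DM:
#' (1) linear over the whole range; (2) linear to 1.38 then plateau;
#' (3) linear to 5.5 then plateau; (4) flat to 1.38, linear to 5.5, then
#' plateau; (5) flat to 1.38 then linear to 22. Each candidate is an
#' intercept-plus-slope model in a piecewise-linear transform of dose, so
#' every fitted mean function is continuous at its breakpoints by
#' construction.
#'
#' @return Tibble with `model`, `name`, `join_point` (dose where the plateau
#'   begins; `NA` when the model has none) and `n_segments`.
#' @export
dose_response_models <- function() {
  tibble::tibble(
    model = 1:5,
    name = c(
      "linear", "linear to 1.38, plateau", "linear to 5.5, plateau",
      "flat to 1.38, linear to 5.5, plateau", "flat to 1.38, linear"
    ),
    join_point = c(NA, 1.38, 5.5, 5.5, NA),
    n_segments = c(1L, 2L, 2L, 3L, 2L)
  )
}

# Piecewise-linear dose transform for candidate m.
dose_transform <- function(m, dose) {
  switch(m,
    dose,
    pmin(dose, 1.38),
    pmin(dose, 5.5),
    pmin(pmax(dose, 1.38), 5.5) - 1.38,
    pmax(dose, 1.38) - 1.38
  )
}

#' Fit the five candidate dose-response models to dose LSMeans
#'
#' Each candidate mean function is fitted by ordinary least squares to the
#' four dose least-squares means (unweighted; the balanced design gives the
#' means a common SEM). The candidate's slope is tested against zero with a
#' t-statistic whose standard error derives from the supplied SEM
#' (`se(slope) = sem / sqrt(Sxx)`) on the pooled ANOVA residual df. The
#' best-fitting model is the one with the smallest slope-test p-value; ties
#' break toward the model with fewer segments, then the lower model number.
#'
#' @param lsmeans Either a numeric vector of four dose means (ordered as
#'   `doses`) or a tibble with columns `dose` and `lsmean`.
#' @param sem Pooled standard error of a dose mean from the ANOVA.
#' @param df_resid Residual degrees of freedom for the slope test
#'   (14 in the standard design).
#' @param doses Dose grid; all four levels must be present.
#' @return Object of class `dose_response_fit`: `models` table with
#'   intercept, slope, plateau level, join point, t statistic and p-value
#'   per candidate; `selected` (model number); plus the inputs.
#' @export
fit_dose_response <- function(lsmeans, sem, df_resid = 14,
                              doses = c(0, 1.38, 5.5, 22.0)) {
  if (is.data.frame(lsmeans)) {
    if (!all(doses %in% lsmeans$dose)) {
      rlang::abort("lsmeans must contain all four dose levels")
    }
    y <- lsmeans$lsmean[match(doses, lsmeans$dose)]
  } else {
    y <- as.numeric(lsmeans)
  }
  if (length(y) != length(doses) || anyNA(y)) {
    rlang::abort("need one mean per dose level")
  }
  if (!isTRUE(sem > 0)) rlang::abort("sem must be a positive scalar")

  spec <- dose_response_models()
  fits <- purrr::map_dfr(spec$model, function(m) {
    x <- dose_transform(m, doses)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    se_slope <- sem / sqrt(sxx)
    tstat <- slope / se_slope
    jp <- spec$join_point[m]
    tibble::tibble(
      model = m,
      intercept = intercept, slope = slope,
      plateau = if (!is.na(jp)) intercept + slope * dose_transform(m, jp) else NA_real_,
      std.error = se_slope, statistic = tstat,
      p.value = 2 * stats::pt(-abs(tstat), df_resid)
    )
  })
  models <- dplyr::left_join(spec, fits, by = "model")
  ord <- order(models$p.value, models$n_segments, models$model)
  structure(
    list(
      models = models, selected = models$model[ord[1]],
      doses = doses, lsmeans = y, sem = sem, df_resid = df_resid
    ),
    class = "dose_response_fit"
  )
}

#' Predicted mean from a candidate dose-response model
#'
#' @param fit A [fit_dose_response()] object.
#' @param dose Numeric vector of doses.
#' @param model Candidate number (default the selected model).
#' @return Predicted response.
#' @export
predict_dose_response <- function(fit, dose, model = fit$selected) {
  row <- fit$models[fit$models$model == model, ]
  row$intercept + row$slope * dose_transform(model, dose)
}

#' Minimum effective dose from planned control contrasts
#'
#' The smallest tested dose whose planned contrast against control is
#' significant (p < 0.05), available only after a significant overall dose
#' F-test (p < 0.05).
#'
#' @param fit Either an [rcbd_fit()] object (its pooled contrasts and dose
#'   F-test are used) or a tibble of contrasts with columns `dose` and
#'   `p.value`, in which case `f_p` must be given.
#' @param f_p Overall dose F-test p-value (ignored when `fit` is an
#'   `rcbd_fit`).
#' @param alpha Significance threshold (0.05).
#' @return List with `dose` (`NA` if undetermined) and `reason`.
#' @export
min_effective_dose <- function(fit, f_p = NULL, alpha = 0.05) {
  if (inherits(fit, "rcbd_fit")) {
    f_p <- fit$anova$p.value[fit$anova$term == "dose"]
    contrasts <- fit$contrasts
  } else {
    contrasts <- fit
    if (is.null(f_p)) rlang::abort("f_p is required with a raw contrast table")
  }
  if (!(f_p < alpha)) {
    return(list(dose = NA_real_, reason = sprintf(
      "overall dose F-test not significant (p = %.3g)", f_p
    )))
  }
  sig <- contrasts$dose[contrasts$p.value < alpha]
  if (length(sig) == 0) {
    return(list(dose = NA_real_, reason = "no contrast vs control significant"))
  }
  list(dose = min(sig), reason = "smallest dose differing from control")
}

#' Maximum effective dose (the join point of the selected model)
#'
#' When the best-fitting candidate is a linear-plateau model with a slope
#' different from zero (p <= 0.05), the maximum effective dose is the join
#' point where its plateau begins. A selected model without a plateau means
#' the response is monotone to the top of the tested range and no maximum
#' effective dose inside it can be declared.
#'
#' @param fit A [fit_dose_response()] object.
#' @param alpha Slope-test threshold (0.05).
#' @return List with `dose` (`NA` if undetermined) and `reason`.
#' @export
max_effective_dose <- function(fit, alpha = 0.05) {
  sel <- fit$models[fit$models$model == fit$selected, ]
  if (sel$p.value > alpha) {
    return(list(dose = NA_real_, reason = sprintf(
      "selected model slope not different from zero (p = %.3g)", sel$p.value
    )))
  }
  if (is.na(sel$join_point)) {
    return(list(
      dose = NA_real_,
      reason = "selected model has no plateau; response monotone to the top dose"
    ))
  }
  list(dose = sel$join_point, reason = "join point of the selected model")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response candidate fits (slope t-test on", x$df_resid, "df)\n")
  print(
    as.data.frame(x$models[, c("model", "name", "slope", "statistic", "p.value")]),
    digits = 4, row.names = FALSE
  )
  sel <- x$models[x$models$model == x$selected, ]
  cat(sprintf("selected: model %d (%s)\n", sel$model, sel$name))
  invisible(x)
}

#' Tidy the candidate table of a dose-response fit
#'
#' @param x A [fit_dose_response()] object.
#' @param ... Unused.
#' @return The per-candidate parameter/test tibble with a `selected` flag.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  dplyr::mutate(x$models, selected = .data$model == x$selected)
}

#' One-row summary of a dose-response fit
#'
#' @param x A [fit_dose_response()] object.
#' @param ... Unused.
#' @return Tibble with the selected model, its p-value and join point.
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  sel <- x$models[x$models$model == x$selected, ]
  tibble::tibble(
    selected = sel$model, name = sel$name, slope = sel$slope,
    p.value = sel$p.value, join_point = sel$join_point
  )
}

#' Plot dose LSMeans with the candidate dose-response curves
#'
#' @param object A [fit_dose_response()] object.
#' @param all_models Draw all five candidates (default) or the selected one.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, all_models = TRUE, ...) {
  grid <- seq(min(object$doses), max(object$doses), length.out = 200)
  which_models <- if (all_models) object$models$model else object$selected
  curves <- purrr::map_dfr(which_models, function(m) {
    tibble::tibble(
      dose = grid,
      fitted = predict_dose_response(object, grid, model = m),
      model = sprintf(
        "%d: %s%s", m, object$models$name[m],
        ifelse(m == object$selected, " (selected)", "")
      )
    )
  })
  pts <- tibble::tibble(dose = object$doses, lsmean = object$lsmeans)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, colour = .data$model)) +
    ggplot2::geom_point(
      data = pts, ggplot2::aes(y = .data$lsmean), size = 2
    ) +
    ggplot2::geom_errorbar(
      data = pts,
      ggplot2::aes(
        ymin = .data$lsmean - object$sem, ymax = .data$lsmean + object$sem
      ),
      width = 0.4
    ) +
    ggplot2::labs(
      x = "dose (mg/kg DM)", y = "response LSMean",
      colour = "candidate"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
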