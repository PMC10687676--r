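#' Bland-Altman agreement between two step-count series
#'
#' Quantifies agreement between two methods measuring the same quantity.
#' With paired measurements `a` and `b`, the differences `d = a - b` give
#' the mean bias `mean(d)` and the limits of agreement
#' `mean(d) +/- 1.96 * sd(d)` (sample SD, n - 1 denominator). The relative
#' bias expresses the mean bias as a percentage of the grand mean of the
#' pairwise averages `(a + b) / 2`.
#'
#' @param data Optional data frame holding the two measurement columns; may
#'   be `NULL` when `a` and `b` are vectors.
#' @param a,b Column names (tidy-selected) or numeric vectors: first and
#'   second method. Differences are `a - b`.
#' @return An object of class `bland_altman`: list with `n`, `mean_bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `relative_bias` (percent), and the
#'   paired data. Supports [tidy()], [glance()], and [ggplot2::autoplot()].
#' @examples
#' bland_altman(data.frame(phone = c(100, 210, 330), ref = c(95, 220, 320)),
#'              phone, ref)
#' @export
bland_altman <- function(data = NULL, a, b) {
  if (is.null(data)) {
    av <- a
    bv <- b
  } else {
    av <- dplyr::pull(data, {{ a }})
    bv <- dplyr::pull(data, {{ b }})
  }
  if (length(av) != length(bv)) {
    abort("paired series must have equal length", class = "stepwave_data_error")
  }
  ok <- !(is.na(av) | is.na(bv))
  av <- av[ok]
  bv <- bv[ok]
  if (length(av) < 2) {
    abort("Bland-Altman needs at least 2 pairs",
          class = "stepwave_insufficient_data")
  }
  d <- av - bv
  m <- (av + bv) / 2
  bias <- mean(d)
  s <- sd(d)
  grand_mean <- mean(m)
  structure(
    list(
      n = length(d),
      mean_bias = bias,
      sd_diff = s,
      loa_low = bias - 1.96 * s,
      loa_high = bias + 1.96 * s,
      relative_bias = if (grand_mean != 0) 100 * bias / grand_mean else NA_real_,
      data = tibble(a = av, b = bv, mean = m, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: n = %d, bias = %.2f (LoA %.2f, %.2f), relative bias = %s\n",
    x$n, x$mean_bias, x$loa_low, x$loa_high,
    ifelse(is.na(x$relative_bias), "NA",
           sprintf("%.1f%%", x$relative_bias))
  ))
  invisible(x)
}

#' @describeIn bland_altman One row per summary statistic.
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(
    term = c("mean_bias", "loa_low", "loa_high", "sd_diff", "relative_bias"),
    estimate = c(x$mean_bias, x$loa_low, x$loa_high, x$sd_diff,
                 x$relative_bias)
  )
}

#' @describeIn bland_altman One-row summary.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, mean_bias = x$mean_bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         relative_bias = x$relative_bias)
}

#' Pair step counts across body locations
#'
#' Cross-body validation compares step counts measured simultaneously at
#' different body locations. Given a bout-level table with one step count per
#' location, every unordered pair of locations present is compared, in the
#' canonical order thigh, waist, chest, arm; the difference convention is
#' first-listed minus second-listed.
#'
#' @param counts A data frame with columns `bout` (identifier), `location`,
#'   and `steps`.
#' @return A tibble with `bout`, `location_a`, `location_b`, `steps_a`,
#'   `steps_b`, one row per location pair per bout.
#' @export
pair_locations <- function(counts) {
  stopifnot(all(c("bout", "location", "steps") %in% names(counts)))
  canon <- c("thigh", "waist", "chest", "arm")
  order_loc <- function(loc) {
    known <- match(loc, canon)
    order(ifelse(is.na(known), length(canon) + rank(loc), known))
  }
  counts |>
    dplyr::group_by(.data$bout) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order_loc(df$location), ]
      if (nrow(df) < 2) {
        return(tibble(location_a = character(), location_b = character(),
                      steps_a = numeric(), steps_b = numeric()))
      }
      pairs <- utils::combn(nrow(df), 2)
      tibble(
        location_a = df$location[pairs[1, ]],
        location_b = df$location[pairs[2, ]],
        steps_a = df$steps[pairs[1, ]],
        steps_b = df$steps[pairs[2, ]]
      )
    }) |>
    dplyr::ungroup()
}

#' Fairness regression of device differences on age and BMI
#'
#' Checks whether the step-count difference between two devices is
#' systematically associated with participant age or body mass index. The
#' linear model is `Y_i = b0 + b_age * age_i + b_bmi * bmi_i + e_i`, fitted
#' by ordinary least squares with t-based 95% confidence intervals; a
#' covariate is flagged as a fairness concern when its CI excludes 0.
#'
#' @param data Data frame with one row per participant.
#' @param diff,age,bmi Column names (tidy-selected): the per-participant step
#'   difference and covariates.
#' @return An object of class `fairness_fit` (`model_kind = "linear"`)
#'   supporting [tidy()] and [glance()].
#' @export
fit_fairness_linear <- function(data, diff, age, bmi) {
  df <- tibble(
    y = dplyr::pull(data, {{ diff }}),
    age = dplyr::pull(data, {{ age }}),
    bmi = dplyr::pull(data, {{ bmi }})
  )
  if (nrow(df) < 4) {
    abort("need more participants than covariates + 1",
          class = "stepwave_insufficient_data")
  }
  fit <- lm(y ~ age + bmi, data = df)
  if (fit$rank < 3) {
    abort("fairness design matrix is rank deficient",
          class = "stepwave_fit_error")
  }
  ci <- suppressWarnings(confint(fit, level = 0.95))
  # summary() warns on zero-residual designs; the zero-width CI branch below
  # handles that case explicitly
  sm <- suppressWarnings(summary(fit))
  coefs <- tibble(
    term = c("(Intercept)", "age", "bmi"),
    estimate = unname(stats::coef(fit)),
    std_error = unname(sm$coefficients[, "Std. Error"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
  # a zero-residual fit has zero-width CIs; confint returns NaN there
  zero_sd <- coefs$std_error == 0 | is.nan(coefs$conf_low)
  coefs$conf_low[zero_sd] <- coefs$estimate[zero_sd]
  coefs$conf_high[zero_sd] <- coefs$estimate[zero_sd]
  new_fairness_fit("linear", coefs, n = nrow(df), fit = fit,
                   sigma = sm$sigma)
}

#' Mixed-effects fairness regression with participant random intercepts
#'
#' When each participant contributes repeated difference observations (for
#' example first day and first day above threshold), observations cluster
#' within participant. The model adds a participant random intercept:
#' `Y_ij = b0 + b_age * age_i + b_bmi * bmi_i + u_i + e_ij`,
#' `u_i ~ N(0, sd_u^2)`. Fixed-effect 95% CIs use the normal approximation
#' `estimate +/- 1.96 * SE`. A singular fit (variance component collapsing
#' to 0) is flagged in the result, not fatal.
#'
#' @param data Data frame with repeated rows per participant.
#' @param diff,age,bmi,id Column names (tidy-selected); `id` identifies the
#'   participant.
#' @return A `fairness_fit` with `model_kind = "mixed_random_intercept"`,
#'   `random_intercept_sd`, `residual_sd`, and `singular` flag.
#' @export
fit_fairness_mixed <- function(data, diff, age, bmi, id) {
  df <- tibble(
    y = dplyr::pull(data, {{ diff }}),
    age = dplyr::pull(data, {{ age }}),
    bmi = dplyr::pull(data, {{ bmi }}),
    id = as.factor(dplyr::pull(data, {{ id }}))
  )
  if (max(table(df$id)) < 2) {
    # one observation per participant: the random intercept is not
    # identifiable and the model degenerates to pooled OLS (sd_u = 0)
    ols <- lm(y ~ age + bmi, data = df)
    sm <- summary(ols)
    est <- stats::coef(ols)
    se <- sm$coefficients[, "Std. Error"]
    z <- qnorm(0.975)
    coefs <- tibble(
      term = c("(Intercept)", "age", "bmi"),
      estimate = unname(est), std_error = unname(se),
      conf_low = unname(est - z * se), conf_high = unname(est + z * se)
    )
    return(new_fairness_fit("mixed_random_intercept", coefs, n = nrow(df),
                            fit = ols, random_intercept_sd = 0,
                            residual_sd = sm$sigma, singular = TRUE,
                            n_groups = nlevels(df$id)))
  }
  fit <- suppressMessages(
    lme4::lmer(y ~ age + bmi + (1 | id), data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  )
  sm <- summary(fit)
  est <- lme4::fixef(fit)
  se <- sm$coefficients[, "Std. Error"]
  z <- qnorm(0.975)
  coefs <- tibble(
    term = c("(Intercept)", "age", "bmi"),
    estimate = unname(est),
    std_error = unname(se),
    conf_low = unname(est - z * se),
    conf_high = unname(est + z * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "id"]
  res_sd <- vc$sdcor[vc$grp == "Residual"]
  new_fairness_fit("mixed_random_intercept", coefs,
                   n = nrow(df), fit = fit,
                   random_intercept_sd = ri_sd, residual_sd = res_sd,
                   singular = lme4::isSingular(fit),
                   n_groups = nlevels(df$id))
}

new_fairness_fit <- function(kind, coefs, n, fit, sigma = NA_real_,
                             random_intercept_sd = NA_real_,
                             residual_sd = NA_real_, singular = FALSE,
                             n_groups = NA_integer_) {
  structure(
    list(model_kind = kind, coefficients = coefs, n = n, fit = fit,
         sigma = sigma, random_intercept_sd = random_intercept_sd,
         residual_sd = residual_sd, singular = singular,
         n_groups = n_groups),
    class = "fairness_fit"
  )
}

#' @export
print.fairness_fit <- function(x, ...) {
  cat(sprintf("Fairness fit (%s), n = %d\n", x$model_kind, x$n))
  print(x$coefficients)
  if (x$model_kind == "mixed_random_intercept") {
    cat(sprintf("random intercept SD = %.2f%s\n", x$random_intercept_sd,
                if (x$singular) " (singular fit)" else ""))
  }
  invisible(x)
}

#' @describeIn fit_fairness_linear Coefficient table with 95% CIs.
#' @param x A `fairness_fit`.
#' @param ... Unused.
#' @export
tidy.fairness_fit <- function(x, ...) {
  x$coefficients
}

#' @describeIn fit_fairness_linear One-row model summary.
#' @export
glance.fairness_fit <- function(x, ...) {
  tibble(
    model_kind = x$model_kind, n = x$n, sigma = x$sigma,
    random_intercept_sd = x$random_intercept_sd,
    residual_sd = x$residual_sd, singular = x$singular
  )
}
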