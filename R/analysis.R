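#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardised sample skewness and kurtosis into the K2
#' statistic, referred to a chi-squared distribution with 2 df. Implemented
#' from the standard published approximations (the same ones behind
#' `scipy.stats.normaltest`). Requires n >= 8.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @return List with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop_input("D'Agostino-Pearson omnibus test requires n >= 8")
  if (stats::sd(x) == 0) stop_input("degenerate input: constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness normalisation (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis normalisation (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Check normality with the study's two tests
#'
#' Runs the D'Agostino-Pearson omnibus and Shapiro-Wilk tests; no automatic
#' action is taken on the result (transform choices are declared per
#' outcome, not driven by the tests). With n < 8 the omnibus test is
#' omitted with a warning; a constant sample triggers a degenerate-input
#' warning and `NA` results.
#'
#' @param values numeric vector.
#' @return Data frame with one row per test: `test`, `statistic`, `p_value`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  out <- data.frame(test = c("dagostino_pearson", "shapiro_wilk"),
                    statistic = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(unique(values)) < 2) {
    warning("degenerate input: constant sample; normality tests not defined")
    return(out)
  }
  if (length(values) < 8) {
    warning("n < 8: omnibus (D'Agostino-Pearson) test omitted")
  } else {
    dp <- dagostino_pearson(values)
    out[1, c("statistic", "p_value")] <- c(dp$statistic, dp$p_value)
  }
  sw <- stats::shapiro.test(values)
  out[2, c("statistic", "p_value")] <- c(unname(sw$statistic), sw$p.value)
  out
}

#' Outcome specification
#'
#' Declares how one outcome enters the treatment-effect model: the
#' transform applied to the raw values before change scores are formed
#' (`sqrt` for the right-skewed component scores — by default whole grains,
#' nuts and legumes, and red and processed meat) and the model covariate
#' (`baseline_energy` for the diet-quality outcomes, `baseline_value` for
#' the secondary BMI and activity outcomes, or `none`).
#'
#' @param name outcome name.
#' @param transform `"identity"` or `"sqrt"`.
#' @param covariate `"baseline_energy"`, `"baseline_value"` or `"none"`.
#' @return List of class `outcome_spec`.
#' @export
outcome_spec <- function(name, transform = c("identity", "sqrt"),
                         covariate = c("baseline_energy", "baseline_value", "none")) {
  structure(list(name = name, transform = match.arg(transform),
                 covariate = match.arg(covariate)),
            class = "outcome_spec")
}

#' Apply an outcome transform
#'
#' @param values numeric vector.
#' @param spec an [outcome_spec()] (or a transform name).
#' @return Transformed values; `sqrt` requires all values >= 0.
#' @export
apply_transform <- function(values, spec) {
  transform <- if (inherits(spec, "outcome_spec")) spec$transform else spec
  switch(transform,
    identity = values,
    sqrt = {
      if (any(values < 0, na.rm = TRUE))
        stop_input("square-root transform requires non-negative values")
      sqrt(values)
    },
    stop_input("unknown transform '%s'", transform))
}

#' ANCOVA treatment effect on change scores
#'
#' Fits the linear model `change ~ group (+ covariate)` and reports the
#' group coefficient as the treatment effect (intervention minus control),
#' with its model-based two-sided 95% t-interval and p-value. Adjusted
#' per-arm changes are the model predictions at the grand mean of the
#' covariate; their SDs are the within-arm residual SDs. With no covariate
#' (or a constant one) the effect reduces exactly to the difference in raw
#' mean changes.
#'
#' @param change numeric change scores (endpoint minus baseline, on the
#'   analysis scale).
#' @param group factor or character with exactly two levels; the first
#'   level (after factoring) is the control/reference arm.
#' @param covariate optional numeric baseline covariate.
#' @param outcome outcome label carried into the result.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `mahei_ancova` with components `effect`,
#'   `ci`, `p_value`, `adjusted` (per-arm mean and SD of adjusted change),
#'   `n` (per arm), and the underlying `lm` fit. Methods: `print`,
#'   `summary`, `coef`, `confint`, `predict`, `residuals`.
#' @examples
#' set.seed(1)
#' grp <- rep(c("control", "pn"), each = 30)
#' chg <- rnorm(60) + 2 * (grp == "pn")
#' fit <- ancova_effect(chg, grp)
#' coef(fit); confint(fit)
#' @export
ancova_effect <- function(change, group, covariate = NULL,
                          outcome = "outcome", conf_level = 0.95) {
  group <- factor(group)
  if (nlevels(group) != 2)
    stop_input("exactly two groups required, got %d", nlevels(group))
  keep <- !is.na(change) & !is.na(group)
  if (!is.null(covariate)) keep <- keep & !is.na(covariate)
  change <- change[keep]; group <- droplevels(group[keep])
  if (any(table(group) < 3)) stop_input("each arm needs n >= 3")
  dat <- data.frame(change = change, group = group)
  if (!is.null(covariate)) {
    covariate <- covariate[keep]
    if (stats::sd(covariate) == 0) {
      covariate <- NULL   # constant covariate carries no information
    } else {
      dat$covariate <- covariate
    }
  }
  form <- if (is.null(covariate)) change ~ group else change ~ group + covariate
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) stop_input("collinear covariate: model not identifiable")
  co <- stats::coef(fit)
  effect <- unname(co[2])
  ci <- unname(stats::confint(fit, level = conf_level)[2, ])
  p <- summary(fit)$coefficients[2, 4]

  grand <- if (is.null(covariate)) NULL else mean(dat$covariate)
  newd <- data.frame(group = factor(levels(group), levels = levels(group)))
  if (!is.null(grand)) newd$covariate <- grand
  adj_mean <- stats::predict(fit, newdata = newd)
  adj_sd <- tapply(stats::residuals(fit), dat$group, stats::sd)
  adjusted <- data.frame(group = levels(group),
                         adj_change = unname(adj_mean),
                         adj_sd = unname(adj_sd[levels(group)]),
                         stringsAsFactors = FALSE)

  structure(list(outcome = outcome, effect = effect, ci = ci, p_value = p,
                 conf_level = conf_level, adjusted = adjusted,
                 n = as.integer(table(group)), arms = levels(group),
                 has_covariate = !is.null(covariate), fit = fit),
            class = "mahei_ancova")
}

#' @export
print.mahei_ancova <- function(x, digits = 2, ...) {
  cat(sprintf("ANCOVA treatment effect — %s\n", x$outcome))
  cat(sprintf("  %s (n=%d) vs %s (n=%d)%s\n", x$arms[2], x$n[2],
              x$arms[1], x$n[1],
              if (x$has_covariate) ", baseline covariate adjusted" else ""))
  cat(sprintf("  effect %s - %s: %.*f (%.0f%% CI %.*f to %.*f), p = %.3g\n",
              x$arms[2], x$arms[1], digits, x$effect, 100 * x$conf_level,
              digits, x$ci[1], digits, x$ci[2], x$p_value))
  invisible(x)
}

#' @export
summary.mahei_ancova <- function(object, ...) {
  print(object)
  cat("\nAdjusted per-arm change (at grand covariate mean):\n")
  print(object$adjusted, row.names = FALSE)
  cat("\nUnderlying linear model:\n")
  print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.mahei_ancova <- function(object, ...) {
  stats::setNames(object$effect, paste0("effect_", object$arms[2]))
}

#' @export
confint.mahei_ancova <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && level != object$conf_level)
    return(unname(stats::confint(object$fit, level = level)[2, ]))
  object$ci
}

#' @export
predict.mahei_ancova <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, ...))
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.mahei_ancova <- function(object, ...) stats::residuals(object$fit, ...)

#' Per-arm sample size from a two-arm power calculation
#'
#' Normal-approximation sample size for detecting a relative increase in a
#' mean: absolute effect = `relative_increase * mean`; per-arm
#' n = ceiling(2 (z_(1-alpha/2) + z_power)^2 / (effect/sd)^2); total =
#' arms x per-arm n. With mean 49.58, SD 9.51, a 6.5% relative increase,
#' alpha 0.05 and power 0.8 this gives a 274-participant recruitment target.
#'
#' @param mean expected control-arm mean of the outcome.
#' @param sd outcome standard deviation (> 0).
#' @param relative_increase relative effect, e.g. 0.065 for +6.5%.
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.8).
#' @param arms number of arms (default 2).
#' @return List with `per_arm`, `total`, `absolute_effect`.
#' @export
power_sample_size <- function(mean, sd, relative_increase,
                              alpha = 0.05, power = 0.8, arms = 2) {
  if (sd <= 0) stop_input("sd must be positive")
  if (power <= 0 || power >= 1) stop_input("power must be in (0, 1)")
  effect <- relative_increase * mean
  if (effect == 0) stop_input("zero effect size: sample size undefined")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  per_arm <- ceiling(2 * z^2 / (effect / sd)^2)
  list(per_arm = per_arm, total = arms * per_arm, absolute_effect = effect)
}

#' Inflate a recruitment target for expected dropout
#'
#' Two conventions are in use: multiplicative (`n * (1 + rate)`) and
#' divisor (`n / (1 - rate)`); both are reported, with the multiplicative
#' value as the default `inflated`. Results are rounded up.
#'
#' @param total_n sample size before dropout.
#' @param dropout_rate expected dropout fraction, in \[0, 1).
#' @return List with `inflated` (multiplicative), `multiplicative`, `divisor`.
#' @export
inflate_for_dropout <- function(total_n, dropout_rate) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_input("dropout_rate must be in [0, 1)")
  mult <- ceiling(total_n * (1 + dropout_rate))
  divi <- ceiling(total_n / (1 - dropout_rate))
  list(inflated = mult, multiplicative = mult, divisor = divi)
}
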