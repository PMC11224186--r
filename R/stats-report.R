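# Cohort statistics: normality-gated paired comparisons, Pearson
# correlations with Fisher-z confidence intervals, regression diagnostics,
# median [IQR] summaries and coefficient of variation.

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences selects the test: paired Student t
#' when the differences look Gaussian (p >= `alpha_normality`), paired
#' Wilcoxon otherwise. Medians and interquartile ranges of both conditions
#' are reported alongside. Constant (including all-zero) differences are
#' degenerate: the result is flagged and p = 1 by convention when all
#' differences are zero.
#'
#' @param x,y paired per-subject values of the two conditions.
#' @param alpha_normality normality gate, default 0.05.
#' @return object of class `paired_comparison`: `test` ("paired_t" or
#'   "wilcoxon"), `statistic`, `p`, `normality_p`, per-condition `median`
#'   and `iqr` (25th/75th), `n`, `flags`.
#' @export
paired_compare <- function(x, y, alpha_normality = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  flags <- character(0)
  if (all(d == 0)) {
    return(structure(list(test = "none", statistic = NA_real_, p = 1,
                          normality_p = NA_real_,
                          median = c(x = stats::median(x), y = stats::median(y)),
                          iqr = rbind(x = stats::quantile(x, c(.25, .75)),
                                      y = stats::quantile(y, c(.25, .75))),
                          n = length(x), flags = "degenerate_zero_differences"),
                     class = "paired_comparison"))
  }
  norm_p <- tryCatch(stats::shapiro.test(d)$p.value,
                     error = function(e) NA_real_)
  if (!is.na(norm_p) && norm_p >= alpha_normality) {
    tt <- stats::t.test(x, y, paired = TRUE)
    test <- "paired_t"
  } else {
    tt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    test <- "wilcoxon"
    if (is.na(norm_p)) flags <- c(flags, "normality_test_failed")
  }
  structure(list(test = test, statistic = unname(tt$statistic),
                 p = tt$p.value, normality_p = norm_p,
                 median = c(x = stats::median(x), y = stats::median(y)),
                 iqr = rbind(x = stats::quantile(x, c(.25, .75)),
                             y = stats::quantile(y, c(.25, .75))),
                 n = length(x), flags = flags),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: p = %.4g (normality p = %.3g, n = %d)\n",
              x$test, x$p, x$normality_p, x$n))
  cat(sprintf("  A: %.3g [%.3g-%.3g]   B: %.3g [%.3g-%.3g]\n",
              x$median[1], x$iqr[1, 1], x$iqr[1, 2],
              x$median[2], x$iqr[2, 1], x$iqr[2, 2]))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with the 95% confidence interval from the
#' Fisher z transform (`tanh(atanh(r) +/- 1.96/sqrt(n-3))`) and the
#' two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors, n >= 4, finite.
#' @return object of class `correlation_result`: `r`, `ci_low`, `ci_high`,
#'   `p`, `n`.
#' @export
pearson_ci <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("need paired vectors of length >= 4", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  r <- max(min(r, 1), -1)
  z <- atanh(r)
  hw <- 1.96 / sqrt(n - 3)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(r = r, ci_low = tanh(z - hw), ci_high = tanh(z + hw),
                 p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f [95%% CI %.3f to %.3f], p = %.4g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Linear regression with influence diagnostics
#'
#' Ordinary least squares of y on x with 95% confidence intervals for slope
#' and intercept, residuals, Cook's distances, leverages (hat values) and a
#' Shapiro-Wilk p-value on the residuals (the linearity check).
#'
#' @param x,y numeric vectors, n >= 4.
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `fitted`, `residuals`, `cooks_distances`,
#'   `leverages`, `residual_normality_p`, `n`.
#' @export
linreg_diagnostics <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("need paired vectors of length >= 4", call. = FALSE)
  if (stats::sd(x) == 0) stop("regression undefined: constant x", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  # an exact fit is legitimate input ("perfect fit" warnings are expected)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  res <- stats::residuals(fit)
  exact_fit <- sum(res^2) <= 1e-20 * max(sum((y - mean(y))^2), 1e-300)
  cooks <- if (exact_fit) rep(0, length(x)) else
    unname(stats::cooks.distance(fit))
  norm_p <- if (stats::sd(res) > 0)
    tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_ci = unname(ci["x", ]),
                 intercept_ci = unname(ci["(Intercept)", ]),
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(res),
                 cooks_distances = cooks,
                 leverages = unname(stats::hatvalues(fit)),
                 residual_normality_p = norm_p,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.3f + %.3f x (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  slope 95%% CI [%.3f, %.3f], intercept 95%% CI [%.3f, %.3f]\n",
              x$slope_ci[1], x$slope_ci[2], x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  residual normality p = %.3g, max Cook's D = %.3g\n",
              x$residual_normality_p, max(x$cooks_distances)))
  invisible(x)
}

#' Median, interquartile range and coefficient of variation
#'
#' Percentiles use linear interpolation (the type-7 convention). The
#' coefficient of variation is `sd / |mean| * 100` with the sample standard
#' deviation; a zero mean makes it undefined (NA with a flag).
#'
#' @param values numeric vector; n >= 1 for the median, n >= 2 for the CV.
#' @param cv compute the coefficient of variation (errors when n < 2)?
#' @return list `median`, `q25`, `q75`, `cv` (percent), `n`, `flags`.
#' @export
cohort_summary <- function(values, cv = TRUE) {
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(.25, .75), type = 7, names = FALSE)
  flags <- character(0)
  if (!cv)
    return(list(median = stats::median(values), q25 = q[1], q75 = q[2],
                cv = NA_real_, n = length(values), flags = flags))
  if (length(values) < 2L) stop("need n >= 2 for the coefficient of variation",
                                call. = FALSE)
  m <- mean(values)
  cv <- if (m == 0) { flags <- "cv_undefined_zero_mean"; NA_real_ }
  else stats::sd(values) / abs(m) * 100
  list(median = stats::median(values), q25 = q[1], q75 = q[2],
       cv = cv, n = length(values), flags = flags)
}
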