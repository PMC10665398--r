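#' Pearson correlation with a two-sided t test
#'
#' Thin wrapper around [stats::cor.test()] returning the product-moment
#' coefficient and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant input")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Ordinary least-squares line for ROC_BP on MEC_K
#'
#' @param x predictor (e.g. MEC_K, mA); must not be constant.
#' @param y response (e.g. ROC_BP, %).
#' @return List with `slope`, `intercept`, `predictions` (fitted values),
#'   `residual_sd` (sqrt(SSR/(n-2))), and the underlying `lm` fit.
#' @export
fit_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("regression undefined for constant x")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       predictions = unname(stats::fitted(fit)),
       residual_sd = summary(fit)$sigma, fit = fit)
}

#' Critical value of the two-sided Grubbs outlier test
#'
#' `G_crit(n, alpha) = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t`
#' the upper `alpha/(2n)` quantile of Student's t on `n - 2` degrees of
#' freedom.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level, default 0.05.
#' @return The critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative two-sided Smirnov-Grubbs outlier screening
#'
#' At each pass the most extreme value (largest `|d - mean| / sd`) is tested
#' against [grubbs_critical()]; if flagged it is removed and the test is
#' repeated on the remainder until nothing is flagged or fewer than 3 values
#' remain.
#'
#' @param differences numeric vector (e.g. predicted - measured residuals).
#' @param alpha significance level, default 0.05.
#' @param iterative repeat after removing each flagged value, default TRUE.
#' @param tol spreads below this are treated as zero (guards against
#'   machine-precision residuals from exact fits), default `1e-8`.
#' @return Integer vector of flagged positions in the original vector, in
#'   the order flagged (empty when none).
#' @export
grubbs_outliers <- function(differences, alpha = 0.05, iterative = TRUE,
                            tol = 1e-8) {
  n0 <- length(differences)
  if (n0 < 3) stop("Grubbs test needs at least 3 values")
  live <- seq_len(n0)
  flagged <- integer(0)
  repeat {
    d <- differences[live]
    n <- length(d)
    if (n < 3) break
    s <- sd(d)
    if (s <= tol) {
      warning("zero standard deviation: no outliers can be flagged")
      break
    }
    g <- abs(d - mean(d)) / s
    i <- which.max(g)
    if (g[i] > grubbs_critical(n, alpha)) {
      flagged <- c(flagged, live[i])
      live <- live[-i]
      if (!iterative) break
    } else break
  }
  flagged
}

#' ANCOVA-style test of parallel regression lines
#'
#' Fits the pooled model `y = b0 + b1*x + b2*g + b3*(x*g)` with a group
#' indicator `g` and reports the two-sided t-test p-value for the
#' interaction (`b3 = 0`, slope equality). The model is then refit without
#' the interaction and the two-sided p-value for `b2 = 0` (intercept
#' equality given a common slope) is reported.
#'
#' @param x1,y1 data for group 1.
#' @param x2,y2 data for group 2.
#' @return List with `p_slope_equality`, `p_intercept_equality`,
#'   `slope_difference`, `intercept_difference`, and the two `lm` fits.
#' @export
parallel_lines_test <- function(x1, y1, x2, y2) {
  stopifnot(length(x1) == length(y1), length(x2) == length(y2))
  if (length(x1) < 3 || length(x2) < 3)
    stop("each group needs at least 3 points")
  if (sd(x1) == 0 || sd(x2) == 0)
    stop("degenerate design: constant x within a group")
  x <- c(x1, x2)
  y <- c(y1, y2)
  g <- rep(c(0, 1), c(length(x1), length(x2)))
  full <- lm(y ~ x * g)
  cf <- summary(full)$coefficients
  if (!("x:g" %in% rownames(cf))) stop("degenerate design")
  reduced <- lm(y ~ x + g)
  cr <- summary(reduced)$coefficients
  list(p_slope_equality = cf["x:g", "Pr(>|t|)"],
       p_intercept_equality = cr["g", "Pr(>|t|)"],
       slope_difference = unname(coef(full)["x:g"]),
       intercept_difference = unname(coef(reduced)["g"]),
       fit_full = full, fit_common_slope = reduced)
}

#' Bland-Altman agreement of predicted vs measured values
#'
#' Differences are taken as `predicted - measured`. The bias is their mean,
#' the limits of agreement are `bias +/- 1.96 * SD`, and the precision is
#' the half-width of the limits, `1.96 * SD`.
#'
#' @param predicted,measured numeric vectors of equal length (n >= 2).
#' @return A `bland_altman` list with `bias`, `sd`, `loa_low`, `loa_high`,
#'   `precision`, `differences`, `means`.
#' @export
bland_altman <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("predicted and measured must have equal length")
  if (length(predicted) < 2) stop("need at least 2 pairs")
  d <- predicted - measured
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 precision = 1.96 * s, differences = d,
                 means = (predicted + measured) / 2),
            class = "bland_altman")
}

#' Power of the regression-slope F test at a given sample size
#'
#' Power of the level-`alpha` F test of the slope in simple linear
#' regression (numerator df 1, denominator df `n - 2`) when the population
#' coefficient of determination is `r2`: the noncentrality parameter is
#' `n * f2` with effect size `f2 = r2 / (1 - r2)`.
#'
#' @param n sample size (>= 3).
#' @param r2 assumed population coefficient of determination, in (0, 1).
#' @param alpha significance level, default 0.05.
#' @return The power (numeric in (0, 1)).
#' @export
regression_power <- function(n, r2, alpha = 0.05) {
  stopifnot(n >= 3, r2 > 0, r2 < 1, alpha > 0, alpha < 1)
  f2 <- r2 / (1 - r2)
  1 - pf(qf(1 - alpha, 1, n - 2), 1, n - 2, ncp = n * f2)
}

#' Minimum sample size for the regression-slope F test
#'
#' Smallest integer `n >= n_min_floor` whose [regression_power()] reaches
#' the target. This is the fixed-model linear-regression formulation of a
#' correlation power analysis (effect size `f2 = R^2 / (1 - R^2)`, one
#' tested predictor). An approximate alternative based on Fisher's
#' z-transformation of the correlation coefficient is available via
#' `method = "fisher_z"`.
#'
#' @param r2_assumed assumed coefficient of determination, in (0, 1).
#' @param alpha significance level, default 0.05.
#' @param power target power, default 0.8.
#' @param n_min_floor smallest admissible n, default 4.
#' @param method `"regression_f"` (default, noncentral F) or `"fisher_z"`
#'   (normal approximation for testing rho = 0).
#' @return The required number of cases (integer).
#' @export
required_sample_size <- function(r2_assumed, alpha = 0.05, power = 0.8,
                                 n_min_floor = 4,
                                 method = c("regression_f", "fisher_z")) {
  method <- match.arg(method)
  stopifnot(r2_assumed > 0, r2_assumed < 1, alpha > 0, alpha < 1,
            power > 0, power < 1, n_min_floor >= 4)
  pw <- function(n) {
    if (method == "regression_f") {
      regression_power(n, r2_assumed, alpha)
    } else {
      rho <- sqrt(r2_assumed)
      z <- atanh(rho) * sqrt(n - 3)
      zc <- stats::qnorm(1 - alpha / 2)
      stats::pnorm(z - zc) + stats::pnorm(-z - zc)
    }
  }
  n <- n_min_floor
  while (pw(n) < power) {
    n <- n + 1
    if (n > 1e6) stop("required power unreachable within n <= 1e6")
  }
  n
}

#' Full cohort-level statistical validation
#'
#' Excludes out-of-range subjects, then computes the Pearson correlation of
#' MEC_K and ROC_BP, the least-squares line, and iterative Grubbs screening
#' of the predicted-minus-measured residuals from that line. When an
#' external prediction equation (e.g. from a prior study under a different
#' anesthetic) is supplied, a Bland-Altman analysis of the externally
#' predicted vs measured ROC_BP is added. When the cohort carries exactly
#' two group labels, a parallel-lines comparison of the two group-wise
#' regressions is added.
#'
#' @param subjects a `cohort` data frame (see [gen_cohort()]) with columns
#'   `subject_id`, `meck_ma` (NA = out of range), `rocbp_pct`, optionally
#'   `out_of_range` and `group`.
#' @param external_equation optional list or named vector with `slope` and
#'   `intercept` of an external prediction line.
#' @param alpha significance level for the Grubbs screening, default 0.05.
#' @return A `cohort_stats_result` list: `n_total`, `n_analyzed`, `r`,
#'   `p_r`, `slope`, `intercept`, `residual_sd`, `predictions`,
#'   `grubbs_outliers` (subject ids), `bland_altman` (or NULL),
#'   `parallel_lines` (or NULL).
#' @export
run_cohort_analysis <- function(subjects, external_equation = NULL,
                                alpha = 0.05) {
  stopifnot(is.data.frame(subjects),
            all(c("meck_ma", "rocbp_pct") %in% names(subjects)))
  oor <- if ("out_of_range" %in% names(subjects)) subjects$out_of_range
  else is.na(subjects$meck_ma)
  keep <- subjects[!oor, , drop = FALSE]
  if (nrow(keep) < 3) stop("need at least 3 in-range subjects")
  x <- keep$meck_ma
  y <- keep$rocbp_pct
  corr <- pearson_correlation(x, y)
  reg <- fit_regression(x, y)
  resid_pm <- reg$predictions - y   # predicted - measured
  out_idx <- grubbs_outliers(resid_pm, alpha = alpha)
  ids <- if ("subject_id" %in% names(keep)) keep$subject_id[out_idx]
  else out_idx
  ba <- NULL
  if (!is.null(external_equation)) {
    ext <- as.list(external_equation)
    ba <- bland_altman(ext$slope * x + ext$intercept, y)
  }
  pl <- NULL
  if ("group" %in% names(keep)) {
    gl <- unique(keep$group[!is.na(keep$group)])
    if (length(gl) == 2) {
      g1 <- keep$group == gl[1] & !is.na(keep$group)
      g2 <- keep$group == gl[2] & !is.na(keep$group)
      pl <- parallel_lines_test(x[g1], y[g1], x[g2], y[g2])
      pl$groups <- as.character(gl)
    }
  }
  structure(list(n_total = nrow(subjects), n_analyzed = nrow(keep),
                 r = corr$r, p_r = corr$p,
                 slope = reg$slope, intercept = reg$intercept,
                 residual_sd = reg$residual_sd,
                 predictions = reg$predictions,
                 grubbs_outliers = ids,
                 bland_altman = ba, parallel_lines = pl),
            class = "cohort_stats_result")
}

#' @export
print.cohort_stats_result <- function(x, ...) {
  cat(sprintf("<cohort_stats_result> n = %d analyzed (of %d)\n",
              x$n_analyzed, x$n_total))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$r, x$p_r))
  cat(sprintf("  ROC_BP = %.3f * MEC_K + %.2f  (residual SD %.2f%%)\n",
              x$slope, x$intercept, x$residual_sd))
  cat(sprintf("  Grubbs outliers: %s\n",
              if (length(x$grubbs_outliers))
                paste(x$grubbs_outliers, collapse = ", ") else "none"))
  if (!is.null(x$bland_altman))
    cat(sprintf("  Bland-Altman bias %.2f%%, precision %.2f%%\n",
                x$bland_altman$bias, x$bland_altman$precision))
  if (!is.null(x$parallel_lines))
    cat(sprintf("  parallel lines: p(slope) = %.3f, p(intercept) = %.3f\n",
                x$parallel_lines$p_slope_equality,
                x$parallel_lines$p_intercept_equality))
  invisible(x)
}
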