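test_that("pearson_correlation matches exact and permutation references", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -3 * x)$r, -1)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")

  # affine invariance / sign flip
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  r0 <- pearson_correlation(a, b)$r
  expect_equal(pearson_correlation(2 * a + 5, b)$r, r0)
  expect_equal(pearson_correlation(-2 * a, b)$r, -r0)

  # two-sided p vs a permutation reference at n = 12
  set.seed(5)
  x <- rnorm(12)
  y <- 0.6 * x + rnorm(12)
  res <- pearson_correlation(x, y)
  nperm <- 20000L
  robs <- abs(cor(x, y))
  hits <- sum(vapply(seq_len(nperm), function(i)
    abs(cor(x, sample(y))) >= robs, logical(1)))
  p_perm <- (hits + 1) / (nperm + 1)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(res$p - p_perm), max(4 * se, 0.01))
})

test_that("fit_regression recovers exact lines and the normal equations", {
  x <- seq(10, 80, 10)
  y <- -0.27 * x + 28.81
  fit <- suppressWarnings(fit_regression(x, y))  # perfect fit by design
  expect_equal(fit$slope, -0.27)
  expect_equal(fit$intercept, 28.81)

  two <- suppressWarnings(fit_regression(c(0, 1, 2), c(5, 7, 9)))
  expect_equal(two$slope, 2)
  expect_equal(two$intercept, 5)

  set.seed(3)
  x <- rnorm(25); y <- rnorm(25)
  fit <- fit_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  slope_ref <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(fit$slope, slope_ref)
  expect_equal(fit$intercept, mean(y) - slope_ref * mean(x))
  expect_error(fit_regression(rep(2, 5), 1:5), "constant")
})

test_that("grubbs_outliers applies the t-based critical value", {
  expect_length(grubbs_outliers(c(-1, 0, 1)), 0)
  expect_equal(grubbs_outliers(c(0, 0.1, -0.1, 0.05, 100)), 5L)
  # iterative removal catches a second masked outlier
  d <- c(rnorm(20, sd = 0.1), 50, 60)
  flagged <- grubbs_outliers(d)
  expect_setequal(flagged, c(21L, 22L))
  expect_warning(grubbs_outliers(rep(1, 5)), "zero standard deviation")
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
})

test_that("grubbs critical value follows the closed form", {
  for (n in c(3, 10, 29)) {
    tq <- qt(1 - 0.05 / (2 * n), n - 2)
    expect_equal(grubbs_critical(n, 0.05),
                 (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)))
  }
})

test_that("parallel_lines_test separates and equates lines correctly", {
  set.seed(6)
  x <- rnorm(20); y <- 2 * x + rnorm(20)
  same <- parallel_lines_test(x, y, x, y)
  expect_equal(same$slope_difference, 0, tolerance = 1e-10)
  expect_equal(same$p_slope_equality, 1, tolerance = 1e-8)

  x1 <- seq(0, 1, length.out = 20)
  sep <- parallel_lines_test(x1, x1 + rnorm(20, sd = 1e-6),
                             x1, -x1 + rnorm(20, sd = 1e-6))
  expect_lt(sep$p_slope_equality, 1e-6)
  expect_error(parallel_lines_test(rep(1, 5), 1:5, 1:5, 1:5), "degenerate")
})

test_that("parallel_lines_test reduces to the explicit ANCOVA computation", {
  set.seed(8)
  for (rep in 1:10) {
    x1 <- rnorm(15); y1 <- rnorm(15)
    x2 <- rnorm(12); y2 <- rnorm(12)
    res <- parallel_lines_test(x1, y1, x2, y2)
    # brute force: full design matrix, closed-form t statistic for the
    # interaction coefficient
    X <- cbind(1, c(x1, x2), rep(c(0, 1), c(15, 12)),
               c(x1, x2) * rep(c(0, 1), c(15, 12)))
    y <- c(y1, y2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res_ss <- sum((y - X %*% beta)^2)
    sigma2 <- res_ss / (length(y) - 4)
    se <- sqrt(sigma2 * solve(t(X) %*% X)[4, 4])
    tstat <- beta[4] / se
    p_ref <- 2 * pt(-abs(tstat), length(y) - 4)
    expect_equal(res$p_slope_equality, p_ref, tolerance = 1e-10)
  }
})

test_that("bland_altman reports bias, limits, and precision", {
  x <- c(10, 12, 14, 16)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$precision, 0)
  off <- bland_altman(x + 2, x)
  expect_equal(off$bias, 2)
  expect_equal(off$sd, 0)
  set.seed(12)
  p <- rnorm(30); m <- rnorm(30)
  ba <- bland_altman(p, m)
  d <- p - m
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd, sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$precision, 1.96 * sd(d))
  expect_true(abs(ba$loa_high - ba$bias) - abs(ba$bias - ba$loa_low) < 1e-12)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("required_sample_size matches the noncentral-F power model", {
  # a huge effect bottoms out at the floor
  expect_equal(required_sample_size(0.99), 4)
  # power at the returned n reaches the target; at n - 1 it does not
  for (r2 in c(0.1, 0.25, 0.52)) {
    n <- required_sample_size(r2)
    expect_gte(regression_power(n, r2), 0.8)
    if (n > 4) expect_lt(regression_power(n - 1, r2), 0.8)
  }
  # monotone in effect size, alpha, and power
  expect_true(all(diff(vapply(c(0.1, 0.2, 0.3, 0.5), required_sample_size,
                              numeric(1))) <= 0))
  expect_gte(required_sample_size(0.25, alpha = 0.01),
             required_sample_size(0.25, alpha = 0.05))
  expect_gte(required_sample_size(0.25, power = 0.9),
             required_sample_size(0.25, power = 0.8))
  # the Fisher-z mode is a coarser approximation but stays in the vicinity
  expect_lt(abs(required_sample_size(0.25, method = "fisher_z") - 26), 6)
})

test_that("moderate-effect sample size verifies by Monte-Carlo power", {
  n <- required_sample_size(0.52)
  expect_equal(n, 10)
  set.seed(14)
  reps <- 20000L
  p_n <- oracle_mc_power(n, 0.52, reps)
  p_n1 <- oracle_mc_power(n - 1, 0.52, reps)
  se <- sqrt(0.8 * 0.2 / reps)
  expect_gte(p_n, 0.8 - 3 * se)
  expect_lt(p_n1, 0.8 + 3 * se)
})

test_that("run_cohort_analysis composes the full validation", {
  # noise-free cohort: perfect negative correlation, no outliers, zero bias
  # against the generating line
  co <- gen_cohort(cohort_config(n_subjects = 30, residual_sd = 0,
                                 seed = 44))
  res <- suppressWarnings(  # perfect fit by construction
    run_cohort_analysis(co, external_equation = list(slope = -0.27,
                                                     intercept = 28.81)))
  expect_equal(res$r, -1)
  expect_warning(
    expect_length(grubbs_outliers(res$predictions -
                                    co$rocbp_pct[!co$out_of_range]), 0),
    "zero standard deviation")
  expect_length(res$grubbs_outliers, 0)
  expect_equal(res$bland_altman$bias, 0, tolerance = 1e-10)
  expect_equal(res$slope, -0.27)
  expect_equal(res$intercept, 28.81)

  # one gross outlier (+10 residual SDs) is exactly the subject flagged
  co2 <- gen_cohort(cohort_config(n_subjects = 30, residual_sd = 5,
                                  seed = 45))
  victim <- which(!co2$out_of_range)[5]
  co2$rocbp_pct[victim] <- co2$rocbp_pct[victim] + 50
  # the gross outlier is flagged first; later iterations may add chance
  # flags at the nominal 5% rate, which is expected of the iterative test
  res2 <- run_cohort_analysis(co2)
  expect_equal(res2$grubbs_outliers[1], co2$subject_id[victim])

  # out-of-range subjects are excluded from the analysis set
  co3 <- gen_cohort(cohort_config(n_subjects = 30, seed = 2))
  res3 <- run_cohort_analysis(co3)
  expect_equal(res3$n_analyzed, sum(!co3$out_of_range))
  expect_error(run_cohort_analysis(co3[co3$out_of_range, , drop = FALSE]),
               "3 in-range")
})

test_that("two-group cohorts trigger the parallel-lines comparison", {
  co <- gen_cohort(cohort_config(
    n_subjects = 60, residual_sd = 3, seed = 46,
    group_labels = c("healthy", "risk")))
  res <- run_cohort_analysis(co)
  expect_false(is.null(res$parallel_lines))
  # both groups share one generating line: no evidence against parallelism
  expect_gt(res$parallel_lines$p_slope_equality, 0.01)

  # forced slope difference is detected
  co2 <- gen_cohort(cohort_config(
    n_subjects = 120, residual_sd = 1, seed = 47,
    group_labels = c("healthy", "risk"),
    group_overrides = list(risk = list(slope = 0.27))))
  res2 <- run_cohort_analysis(co2)
  expect_lt(res2$parallel_lines$p_slope_equality, 1e-6)
})
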