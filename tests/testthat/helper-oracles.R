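# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# MEC_K by exhaustive suffix scan: try every intensity as a candidate and
# accept the smallest one for which every tested intensity at or above it
# responded; no candidate (equivalently, top intensity silent) => OOR (NA).
oracle_meck_suffix <- function(responded, intensities = seq(10, 80, 10)) {
  for (i in seq_along(intensities)) {
    if (all(responded[i:length(responded)])) return(intensities[i])
  }
  NA_real_
}

# Two-unknown no-intercept least squares via explicit normal equations.
oracle_fit_normal_eq <- function(dPl, dPl_dot, dPb) {
  a11 <- sum(dPl^2); a12 <- sum(dPl * dPl_dot); a22 <- sum(dPl_dot^2)
  b1 <- sum(dPl * dPb); b2 <- sum(dPl_dot * dPb)
  det <- a11 * a22 - a12^2
  c((a22 * b1 - a12 * b2) / det, (a11 * b2 - a12 * b1) / det)
}

# Windowed pre-median / post-max by explicit enumeration over beats.
oracle_window_stats <- function(times, k, onset, offset,
                                pre_s = 10, post_s = 20) {
  pre <- k[times >= onset - pre_s & times < onset]
  post <- k[times > offset & times <= offset + post_s]
  c(pre = median(pre), post = max(post))
}

# Fixed-design Monte-Carlo power of the regression slope test: predictor
# fixed, slope set so the noncentrality equals n * f2 (sigma = 1).
oracle_mc_power <- function(n, r2, reps, alpha = 0.05) {
  f2 <- r2 / (1 - r2)
  x <- seq_len(n) - (n + 1) / 2
  beta <- sqrt(n * f2 / sum(x^2))
  tcrit <- qt(1 - alpha / 2, n - 2)
  hits <- 0L
  for (j in seq_len(reps)) {
    y <- beta * x + rnorm(n)
    r <- cor(x, y)
    if (abs(r * sqrt((n - 2) / (1 - r^2))) > tcrit) hits <- hits + 1L
  }
  hits / reps
}
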