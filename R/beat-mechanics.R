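#' Construct a waveform record
#'
#' Bundles time-aligned arterial-pressure and PPG samples with beat-onset
#' annotations into the container consumed by [segment_beats()] and
#' [estimate_k_series()].
#'
#' @param time_s numeric vector of strictly increasing sample times (s).
#' @param abp_mmhg arterial blood pressure Pb(t) per sample (mmHg).
#' @param ppg_pct PPG amplitude Pl(t) per sample, in percent of full scale.
#' @param sample_rate_hz sampling rate (Hz).
#' @param beat_onsets strictly increasing 1-based sample indices, one per
#'   beat onset (each onset is the t0 of its beat).
#'
#' @return An object of class `waveform_record`: a list with the five fields
#'   above.
#' @export
waveform_record <- function(time_s, abp_mmhg, ppg_pct, sample_rate_hz,
                            beat_onsets) {
  n <- length(time_s)
  if (length(abp_mmhg) != n || length(ppg_pct) != n)
    stop("time_s, abp_mmhg and ppg_pct must have equal length")
  if (n >= 2 && any(diff(time_s) <= 0))
    stop("sample times must be strictly increasing")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive number")
  beat_onsets <- as.integer(beat_onsets)
  if (any(beat_onsets < 1L) || any(beat_onsets > n))
    stop("beat_onsets out of bounds")
  if (length(beat_onsets) >= 2 && any(diff(beat_onsets) <= 0L))
    stop("beat_onsets must be strictly increasing")
  structure(
    list(time_s = as.numeric(time_s), abp_mmhg = as.numeric(abp_mmhg),
         ppg_pct = as.numeric(ppg_pct), sample_rate_hz = sample_rate_hz,
         beat_onsets = beat_onsets),
    class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %d samples @ %g Hz, %d beat onsets\n",
              length(x$time_s), x$sample_rate_hz, length(x$beat_onsets)))
  invisible(x)
}

#' First time derivative of a PPG amplitude series
#'
#' Central finite differences at interior samples, one-sided differences at
#' the two edges. Units are %/s when the input is in percent.
#'
#' @param ppg_pct numeric vector of PPG amplitudes (>= 3 finite samples).
#' @param sample_rate_hz sampling rate (Hz).
#' @return Numeric vector of the same length, the derivative estimate.
#' @export
differentiate_ppg <- function(ppg_pct, sample_rate_hz) {
  n <- length(ppg_pct)
  if (n < 3) stop("differentiate_ppg needs at least 3 samples")
  if (!all(is.finite(ppg_pct))) stop("non-finite PPG samples")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive number")
  d <- numeric(n)
  d[2:(n - 1)] <- (ppg_pct[3:n] - ppg_pct[1:(n - 2)]) * sample_rate_hz / 2
  d[1] <- (ppg_pct[2] - ppg_pct[1]) * sample_rate_hz
  d[n] <- (ppg_pct[n] - ppg_pct[n - 1]) * sample_rate_hz
  d
}

#' Split a waveform record into per-beat segments
#'
#' One segment per inter-onset interval `[onset_i, onset_{i+1})`. Within each
#' segment the pressure, PPG and PPG-derivative series are differenced
#' against the segment's own onset sample (t0), so all three difference
#' series are exactly zero at the first sample. The PPG derivative is
#' computed once over the whole record with [differentiate_ppg()].
#'
#' Segments with fewer than 3 samples are skipped with a warning.
#'
#' @param waveform a [waveform_record()].
#' @return A list of `beat_segment` objects, each a list with fields
#'   `t0_index`, `beat_time_s`, `dPb` (mmHg), `dPl` (%), `dPl_dot` (%/s).
#' @export
segment_beats <- function(waveform) {
  stopifnot(inherits(waveform, "waveform_record"))
  on <- waveform$beat_onsets
  if (length(on) < 2) {
    warning("fewer than 2 beat onsets: no segments")
    return(list())
  }
  pl_dot <- differentiate_ppg(waveform$ppg_pct, waveform$sample_rate_hz)
  segs <- vector("list", length(on) - 1L)
  keep <- logical(length(segs))
  for (i in seq_along(segs)) {
    idx <- on[i]:(on[i + 1L] - 1L)
    if (length(idx) < 3) {
      warning(sprintf("segment %d has fewer than 3 samples; skipped", i))
      next
    }
    t0 <- on[i]
    segs[[i]] <- structure(
      list(t0_index = t0,
           beat_time_s = waveform$time_s[t0],
           dPb = waveform$abp_mmhg[idx] - waveform$abp_mmhg[t0],
           dPl = waveform$ppg_pct[idx] - waveform$ppg_pct[t0],
           dPl_dot = pl_dot[idx] - pl_dot[t0]),
      class = "beat_segment")
    keep[i] <- TRUE
  }
  segs[keep]
}

#' Least-squares fit of the spring-damper impedance model for one beat
#'
#' Fits `dPb = K * dPl + B * dPl_dot` by ordinary least squares with no
#' intercept (all three difference series vanish at the onset sample by
#' construction, so the model passes through the origin). The coefficient of
#' determination is computed against the centred total sum of squares,
#' `R^2 = 1 - SSR / sum((dPb - mean(dPb))^2)`.
#'
#' A beat is `valid` only if the design has full rank, the pressure series is
#' not constant, `R^2 >= r2_min`, and both K and B are non-negative; the
#' exclusion reason is recorded otherwise.
#'
#' @param segment a `beat_segment` from [segment_beats()].
#' @param r2_min minimum coefficient of determination for a valid beat
#'   (default 0.95).
#' @return An object of class `beat_estimate`: list with `beat_time_s`, `k`
#'   (mmHg/%), `b` (mmHg*s/%), `r_squared`, `valid`, `reason` (one of
#'   `"ok"`, `"rank_deficient"`, `"zero_variance"`, `"low_r2"`,
#'   `"negative_coef"`).
#' @export
fit_beat <- function(segment, r2_min = 0.95) {
  stopifnot(inherits(segment, "beat_segment"))
  out <- list(beat_time_s = segment$beat_time_s, k = NA_real_, b = NA_real_,
              r_squared = NA_real_, valid = FALSE, reason = "ok")
  X <- cbind(dPl = segment$dPl, dPl_dot = segment$dPl_dot)
  y <- segment$dPb
  qrX <- qr(X)
  if (qrX$rank < 2L) {
    out$reason <- "rank_deficient"
    return(structure(out, class = "beat_estimate"))
  }
  beta <- qr.coef(qrX, y)
  out$k <- unname(beta[1]); out$b <- unname(beta[2])
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    out$reason <- "zero_variance"
    return(structure(out, class = "beat_estimate"))
  }
  ssr <- sum((y - X %*% beta)^2)
  out$r_squared <- 1 - ssr / sst
  if (out$r_squared < r2_min) {
    out$reason <- "low_r2"
  } else if (out$k < 0 || out$b < 0) {
    out$reason <- "negative_coef"
  } else {
    out$valid <- TRUE
  }
  structure(out, class = "beat_estimate")
}

#' Apply the beat-quality exclusion filter and assemble a K series
#'
#' Retains beats whose coefficient of determination is at least `r2_min` and
#' whose K and B are both non-negative; everything else is excluded, with
#' counts recorded by reason. Order is preserved.
#'
#' @param estimates list of `beat_estimate` objects from [fit_beat()].
#' @param r2_min minimum coefficient of determination (default 0.95).
#' @return A `k_series`: data frame with columns `beat_time_s`, `k`, holding
#'   valid beats only, with attribute `exclusions` (named integer vector of
#'   counts by reason).
#' @export
filter_estimates <- function(estimates, r2_min = 0.95) {
  if (length(estimates) == 0)
    return(k_series(numeric(0), numeric(0),
                    exclusions = integer(0)))
  ok <- vapply(estimates, function(e) {
    isTRUE(is.finite(e$r_squared) && e$r_squared >= r2_min &&
             is.finite(e$k) && is.finite(e$b) && e$k >= 0 && e$b >= 0)
  }, logical(1))
  reasons <- vapply(estimates, function(e) e$reason, character(1))
  excl <- table(reasons[!ok])
  kept <- estimates[ok]
  k_series(vapply(kept, `[[`, numeric(1), "beat_time_s"),
           vapply(kept, `[[`, numeric(1), "k"),
           exclusions = setNames(as.integer(excl), names(excl)))
}

#' Construct a per-beat K series
#'
#' @param beat_time_s strictly increasing beat times (s).
#' @param k per-beat vascular stiffness values (mmHg/%).
#' @param exclusions optional named integer vector of exclusion counts.
#' @return A `k_series` data frame.
#' @export
k_series <- function(beat_time_s, k, exclusions = NULL) {
  if (length(beat_time_s) != length(k))
    stop("beat_time_s and k must have equal length")
  if (length(beat_time_s) >= 2 && any(diff(beat_time_s) <= 0))
    stop("beat times must be strictly increasing")
  structure(data.frame(beat_time_s = as.numeric(beat_time_s),
                       k = as.numeric(k)),
            exclusions = exclusions,
            class = c("k_series", "data.frame"))
}

#' Estimate the per-beat K series from a waveform record
#'
#' Convenience wrapper chaining [segment_beats()], [fit_beat()] and
#' [filter_estimates()].
#'
#' @inheritParams segment_beats
#' @inheritParams fit_beat
#' @return A list with `estimates` (data frame of every fitted beat:
#'   `beat_time_s`, `k`, `b`, `r_squared`, `valid`, `reason`) and `kseries`
#'   (the filtered [k_series()]).
#' @export
estimate_k_series <- function(waveform, r2_min = 0.95) {
  segs <- segment_beats(waveform)
  ests <- lapply(segs, fit_beat, r2_min = r2_min)
  tab <- data.frame(
    beat_time_s = vapply(ests, `[[`, numeric(1), "beat_time_s"),
    k = vapply(ests, `[[`, numeric(1), "k"),
    b = vapply(ests, `[[`, numeric(1), "b"),
    r_squared = vapply(ests, `[[`, numeric(1), "r_squared"),
    valid = vapply(ests, `[[`, logical(1), "valid"),
    reason = vapply(ests, `[[`, character(1), "reason"))
  list(estimates = tab, kseries = filter_estimates(ests, r2_min = r2_min))
}
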