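#' Configuration for the synthetic beat-waveform generator
#'
#' Defaults describe a typical adult under stable anesthesia: 60 bpm, PPG
#' pulse amplitude 8% of full scale, diastolic baseline 80 mmHg, stiffness
#' K = 5 mmHg/% and viscosity B = 0.5 mmHg*s/%, sampled at 100 Hz.
#'
#' @param n_beats number of beats to generate.
#' @param sample_rate_hz sampling rate (Hz), default 100.
#' @param heart_rate_bpm heart rate (beats/min), default 60.
#' @param k_true ground-truth vascular stiffness (mmHg per % PPG).
#' @param b_true ground-truth vascular viscosity (mmHg*s per % PPG).
#' @param ppg_pulse_amplitude_pct peak-to-trough PPG pulse amplitude (%).
#' @param baseline_pressure_mmhg pressure at each beat onset (mmHg).
#' @param noise_sd_mmhg standard deviation of additive i.i.d. Gaussian
#'   pressure noise (mmHg), >= 0.
#' @param seed integer RNG seed.
#' @return A `waveform_config` list.
#' @export
waveform_config <- function(n_beats, sample_rate_hz = 100,
                            heart_rate_bpm = 60, k_true = 5, b_true = 0.5,
                            ppg_pulse_amplitude_pct = 8,
                            baseline_pressure_mmhg = 80,
                            noise_sd_mmhg = 0.5, seed = 1L) {
  stopifnot(n_beats >= 1, sample_rate_hz > 0, heart_rate_bpm > 0,
            k_true > 0, b_true > 0, ppg_pulse_amplitude_pct > 0,
            noise_sd_mmhg >= 0)
  cfg <- list(n_beats = as.integer(n_beats), sample_rate_hz = sample_rate_hz,
              heart_rate_bpm = heart_rate_bpm, k_true = k_true,
              b_true = b_true,
              ppg_pulse_amplitude_pct = ppg_pulse_amplitude_pct,
              baseline_pressure_mmhg = baseline_pressure_mmhg,
              noise_sd_mmhg = noise_sd_mmhg, seed = as.integer(seed))
  if (sample_rate_hz * 60 / heart_rate_bpm < 8)
    stop("configuration error: fewer than 8 samples per beat")
  structure(cfg, class = "waveform_config")
}

#' Generate a synthetic ABP/PPG waveform obeying the impedance model
#'
#' Each beat's PPG pulse is a raised-cosine single hump (smooth, zero value
#' and zero slope at both beat boundaries). The arterial pressure is built
#' forward from the spring-damper model: within each beat,
#' `Pb(t) = Pb(t0) + K*dPl(t) + B*dPl_dot(t) + e`, with `e` i.i.d.
#' `Normal(0, noise_sd^2)`. The derivative entering the forward model is the
#' same discrete central-difference operator used in estimation
#' ([differentiate_ppg()]), so with `noise_sd_mmhg = 0` the downstream fit
#' recovers (K, B) exactly (to numerical round-off).
#'
#' @param config a [waveform_config()].
#' @return A [waveform_record()] with `n_beats` beat onsets and attributes
#'   `k_true`, `b_true`, `config`.
#' @export
gen_beat_waveform <- function(config) {
  stopifnot(inherits(config, "waveform_config"))
  spb <- round(config$sample_rate_hz * 60 / config$heart_rate_bpm)
  if (spb < 8) stop("configuration error: fewer than 8 samples per beat")
  fs <- config$sample_rate_hz
  n <- config$n_beats * spb
  t <- (seq_len(n) - 1) / fs
  period <- spb / fs
  pl <- config$ppg_pulse_amplitude_pct / 2 * (1 - cos(2 * pi * t / period))
  pl_dot <- differentiate_ppg(pl, fs)
  onsets <- seq.int(1L, by = spb, length.out = config$n_beats)
  set.seed(config$seed)
  eps <- rnorm(n, sd = config$noise_sd_mmhg)
  pb <- numeric(n)
  bounds <- c(onsets, n + 1L)
  for (i in seq_along(onsets)) {
    idx <- bounds[i]:(bounds[i + 1L] - 1L)
    o <- onsets[i]
    pb[idx] <- config$baseline_pressure_mmhg +
      config$k_true * (pl[idx] - pl[o]) +
      config$b_true * (pl_dot[idx] - pl_dot[o]) + eps[idx]
  }
  # onset samples carry the exact baseline so each segment's t0 is noise-free
  pb[onsets] <- config$baseline_pressure_mmhg
  wf <- waveform_record(t, pb, pl, fs, onsets)
  attr(wf, "k_true") <- config$k_true
  attr(wf, "b_true") <- config$b_true
  attr(wf, "config") <- config
  wf
}

#' Generate a synthetic per-beat systolic-BP series around a skin incision
#'
#' Pre-incision beats fluctuate about `pre_level`; after the incision the
#' systolic pressure ramps linearly to a peak of
#' `pre_level * (1 + rise_fraction)` and then plateaus. With `noise_sd = 0`
#' the percent change computed by [compute_rocbp()] equals
#' `100 * rise_fraction` exactly.
#'
#' @param pre_level pre-incision systolic pressure level (mmHg), > 0.
#' @param rise_fraction fractional post-incision rise (0.2 means +20%).
#' @param n_pre_beats number of pre-incision beats (>= 10).
#' @param n_post_beats number of post-incision beats (default 60).
#' @param noise_sd additive Gaussian beat-to-beat noise SD (mmHg), >= 0.
#' @param beat_interval_s inter-beat interval (s), default 1.
#' @param rise_beats beats from incision to peak (default 30).
#' @param seed integer RNG seed.
#' @return List with `sbp` (data frame `beat_time_s`, `sbp_mmhg`),
#'   `incision_time_s`, and `rise_fraction_true`.
#' @export
gen_incision_series <- function(pre_level, rise_fraction, n_pre_beats = 30,
                                n_post_beats = 60, noise_sd = 0,
                                beat_interval_s = 1, rise_beats = 30,
                                seed = 1L) {
  if (pre_level <= 0) stop("pre_level must be positive")
  if (n_pre_beats < 10)
    stop("n_pre_beats must be >= 10 (ROC_BP needs 10 pre-incision beats)")
  stopifnot(noise_sd >= 0, n_post_beats >= 1)
  set.seed(seed)
  n <- n_pre_beats + n_post_beats
  tt <- (seq_len(n) - 1) * beat_interval_s
  incision <- tt[n_pre_beats] + beat_interval_s / 2
  peak <- pre_level * (1 + rise_fraction)
  ramp <- pmin(seq_len(n_post_beats) / rise_beats, 1)
  sbp <- c(rep(pre_level, n_pre_beats),
           pre_level + (peak - pre_level) * ramp)
  sbp <- sbp + rnorm(n, sd = noise_sd)
  list(sbp = data.frame(beat_time_s = tt, sbp_mmhg = sbp),
       incision_time_s = incision, rise_fraction_true = rise_fraction)
}
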