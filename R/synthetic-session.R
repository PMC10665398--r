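#' Configuration for a synthetic tetanic-stimulation session
#'
#' A session delivers a ladder of tetanic stimuli (default 10-80 mA in 10-mA
#' steps, 50 Hz for 5 s) over a per-beat K series. Stimuli at or above the
#' subject's threshold evoke a transient multiplicative rise in K (linear
#' rise to peak within 20 s of stimulus offset, then exponential decay);
#' stimuli below threshold evoke nothing. Baseline K fluctuates with a small
#' coefficient of variation (default 1%) so that baseline noise alone never
#' crosses the 5% response criterion. An isolated artifactual spike can be
#' injected at one sub-threshold intensity to exercise noise rejection.
#'
#' @param threshold_ma subject's true response threshold: an intensity from
#'   `intensities_ma`, or `Inf` for a subject that never responds.
#' @param intensities_ma ordered stimulus ladder (mA), default
#'   `seq(10, 80, 10)`.
#' @param stim_duration_s stimulus train duration (s), default 5.
#' @param inter_stimulus_gap_s gap from stimulus offset to the next onset
#'   (s); must be long enough for the evoked transient to decay back to
#'   baseline, default 60.
#' @param evoked_gain function mapping intensity (mA) to the fractional K
#'   rise for at/above-threshold stimuli; default
#'   `0.08 + 0.002 * (i - threshold)`. Must be >= 0.05 at and above
#'   threshold.
#' @param baseline_k baseline vascular stiffness (mmHg/%), default 10.
#' @param baseline_cv coefficient of variation of baseline K fluctuation,
#'   default 0.01 (must be <= 0.01 so the 5% criterion is never met
#'   spuriously).
#' @param spike_at_ma optional sub-threshold intensity at which a single
#'   artifactual >= 5% spike is injected.
#' @param rise_s time from stimulus offset to transient peak (s), default 10
#'   (within the 20-s post-stimulus window).
#' @param decay_tau_s exponential decay time constant (s), default 5.
#' @param beat_interval_s inter-beat interval of the K series (s), default 1.
#' @param seed integer RNG seed.
#' @return A `session_config` list.
#' @export
session_config <- function(threshold_ma, intensities_ma = seq(10, 80, 10),
                           stim_duration_s = 5, inter_stimulus_gap_s = 60,
                           evoked_gain = NULL, baseline_k = 10,
                           baseline_cv = 0.01, spike_at_ma = NULL,
                           rise_s = 10, decay_tau_s = 5,
                           beat_interval_s = 1, seed = 1L) {
  stopifnot(length(intensities_ma) >= 1, all(diff(intensities_ma) > 0),
            stim_duration_s > 0, baseline_k > 0, baseline_cv >= 0,
            rise_s > 0, rise_s <= 20, decay_tau_s > 0, beat_interval_s > 0)
  if (!is.infinite(threshold_ma) && !(threshold_ma %in% intensities_ma))
    stop("threshold_ma must be one of intensities_ma or Inf")
  if (baseline_cv > 0.01)
    stop("baseline_cv must be <= 0.01 so baseline fluctuation alone never ",
         "produces a >= 5% windowed rise")
  if (is.null(evoked_gain)) {
    thr <- threshold_ma
    evoked_gain <- function(i) ifelse(i >= thr, 0.08 + 0.002 * (i - thr), 0)
  }
  g <- vapply(intensities_ma, evoked_gain, numeric(1))
  if (any(intensities_ma >= threshold_ma & g < 0.05))
    stop("evoked_gain must be >= 0.05 at and above threshold_ma")
  if (!is.null(spike_at_ma) && !(spike_at_ma %in% intensities_ma))
    stop("spike_at_ma must be one of intensities_ma")
  # the transient must be back within baseline_cv of baseline before the
  # next stimulus' pre-window opens
  gmax <- max(c(g, if (!is.null(spike_at_ma)) 0.08 else 0))
  settle <- inter_stimulus_gap_s - rise_s - 10
  if (gmax >= 0.05 && (settle <= 0 ||
                       gmax * exp(-settle / decay_tau_s) > baseline_cv))
    stop("configuration error: inter_stimulus_gap_s too short for the ",
         "evoked transient to decay back to baseline")
  structure(list(threshold_ma = threshold_ma,
                 intensities_ma = intensities_ma,
                 stim_duration_s = stim_duration_s,
                 inter_stimulus_gap_s = inter_stimulus_gap_s,
                 evoked_gain = evoked_gain, baseline_k = baseline_k,
                 baseline_cv = baseline_cv, spike_at_ma = spike_at_ma,
                 rise_s = rise_s, decay_tau_s = decay_tau_s,
                 beat_interval_s = beat_interval_s, seed = as.integer(seed)),
            class = "session_config")
}

#' Generate a synthetic stimulation session with known threshold
#'
#' @param config a [session_config()].
#' @return A list of class `stim_session` with `kseries` (a [k_series()]),
#'   `events` (data frame `onset_s`, `intensity_ma`, `duration_s`,
#'   `frequency_hz`), and `threshold_ma` (the ground truth).
#' @export
gen_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  n_stim <- length(config$intensities_ma)
  step <- config$stim_duration_s + config$inter_stimulus_gap_s
  onsets <- 30 + (seq_len(n_stim) - 1) * step
  offsets <- onsets + config$stim_duration_s
  t_end <- offsets[n_stim] + 30
  tt <- seq(0, t_end, by = config$beat_interval_s)
  k <- config$baseline_k * (1 + config$baseline_cv * rnorm(length(tt)))
  shape <- function(dt) {
    s <- numeric(length(dt))
    up <- dt >= 0 & dt <= config$rise_s
    dn <- dt > config$rise_s
    s[up] <- dt[up] / config$rise_s
    s[dn] <- exp(-(dt[dn] - config$rise_s) / config$decay_tau_s)
    s
  }
  for (j in seq_len(n_stim)) {
    i <- config$intensities_ma[j]
    gain <- if (i >= config$threshold_ma) config$evoked_gain(i) else 0
    if (!is.null(config$spike_at_ma) && i == config$spike_at_ma &&
        i < config$threshold_ma)
      gain <- 0.08
    if (gain > 0) k <- k * (1 + gain * shape(tt - offsets[j]))
  }
  structure(
    list(kseries = k_series(tt, k),
         events = data.frame(onset_s = onsets,
                             intensity_ma = config$intensities_ma,
                             duration_s = config$stim_duration_s,
                             frequency_hz = 50),
         threshold_ma = config$threshold_ma),
    class = "stim_session")
}
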