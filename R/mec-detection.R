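#' Score a single tetanic stimulus against the per-beat K series
#'
#' The pre-stimulus K is the median of valid beats in the 10 s before
#' stimulus onset, `[onset - pre_window_s, onset)`; the post-stimulus K is
#' the maximum over the 20 s after stimulus offset,
#' `(offset, offset + post_window_s]`. The stimulus "responded" when the
#' relative rise `post/pre - 1` reaches `threshold` (default 5%). The median
#' of an even number of beats is the mean of the two middle values.
#'
#' @param kseries a [k_series()] of valid beats.
#' @param event one-row data frame or list with `onset_s`, `intensity_ma`
#'   and `duration_s` (stimulus train length, default 5 s).
#' @param pre_window_s pre-stimulus window length (s), default 10.
#' @param post_window_s post-stimulus window length (s), default 20.
#' @param threshold relative-rise response criterion, default 0.05.
#' @param anchor whether the post window starts at the stimulus `"offset"`
#'   (default: after the 5-s train ends) or at its `"onset"`.
#' @return A `stimulus_response`: list with `intensity_ma`, `pre_k`,
#'   `post_k`, `rise`, `responded`.
#' @export
evaluate_stimulus <- function(kseries, event, pre_window_s = 10,
                              post_window_s = 20, threshold = 0.05,
                              anchor = c("offset", "onset")) {
  anchor <- match.arg(anchor)
  onset <- event$onset_s
  dur <- if (!is.null(event$duration_s)) event$duration_s else 5
  ref <- if (anchor == "offset") onset + dur else onset
  pre_idx <- kseries$beat_time_s >= onset - pre_window_s &
    kseries$beat_time_s < onset
  post_idx <- kseries$beat_time_s > ref &
    kseries$beat_time_s <= ref + post_window_s
  if (!any(pre_idx))
    stop(sprintf("no valid beats in the pre-stimulus window [%g, %g)",
                 onset - pre_window_s, onset))
  if (!any(post_idx))
    stop(sprintf("no valid beats in the post-stimulus window (%g, %g]",
                 ref, ref + post_window_s))
  pre_k <- median(kseries$k[pre_idx])
  post_k <- max(kseries$k[post_idx])
  rise <- post_k / pre_k - 1
  structure(list(intensity_ma = event$intensity_ma, pre_k = pre_k,
                 post_k = post_k, rise = rise,
                 responded = rise >= threshold),
            class = "stimulus_response")
}

#' Determine MEC_K from the ladder of stimulus responses
#'
#' Implements the 5% response criterion with noise rejection. Under the
#' default `"suffix"` rule, MEC_K is the smallest intensity from which
#' every tested intensity at or above it responded; isolated responses below
#' that point are rejected as noise. If the highest tested intensity (80 mA
#' on the standard ladder) did not respond, the subject is classified
#' out-of-range. The `"pairwise"` rule is the literal local reading: a
#' responded intensity is rejected as noise when the next stimulus in the
#' ladder did not respond, and MEC_K is the lowest non-rejected responded
#' intensity (still out-of-range when the top intensity did not respond).
#' Both rules agree on every response pattern in which responses are
#' monotone after noise removal, including the canonical worked example
#' (rise at 20 mA rejected, MEC_K = 50 mA).
#'
#' @param responses list of `stimulus_response` objects (or a data frame
#'   with columns `intensity_ma`, `responded`), sorted by increasing
#'   intensity on a complete 10-mA ladder starting at 10 mA.
#' @param rule `"suffix"` (default) or `"pairwise"`.
#' @return A `mec_result`: list with `meck_ma` (numeric, `NA` when
#'   out-of-range), `out_of_range`, `responses` (data frame), and
#'   `rejected_as_noise` (intensities).
#' @export
detect_meck <- function(responses, rule = c("suffix", "pairwise")) {
  rule <- match.arg(rule)
  if (is.data.frame(responses)) {
    tab <- responses
  } else {
    tab <- data.frame(
      intensity_ma = vapply(responses, `[[`, numeric(1), "intensity_ma"),
      pre_k = vapply(responses, function(r)
        if (is.null(r$pre_k)) NA_real_ else r$pre_k, numeric(1)),
      post_k = vapply(responses, function(r)
        if (is.null(r$post_k)) NA_real_ else r$post_k, numeric(1)),
      rise = vapply(responses, function(r)
        if (is.null(r$rise)) NA_real_ else r$rise, numeric(1)),
      responded = vapply(responses, `[[`, logical(1), "responded"))
  }
  ii <- tab$intensity_ma
  if (length(ii) < 1) stop("no stimulus responses supplied")
  if (ii[1] != 10 || (length(ii) > 1 && any(diff(ii) != 10)))
    stop("stimulus ladder must be complete in 10-mA steps starting at 10 mA")
  r <- tab$responded
  n <- length(r)
  if (rule == "suffix") {
    if (!r[n]) {
      meck <- NA_real_
    } else {
      # smallest index from which the whole suffix responded
      first <- n
      while (first > 1 && r[first - 1]) first <- first - 1
      meck <- ii[first]
    }
  } else {
    rejected <- r & c(!r[-1], FALSE)          # responded but next did not
    candidate <- r & !rejected
    meck <- if (!r[n] || !any(candidate)) NA_real_ else min(ii[candidate])
  }
  oor <- is.na(meck)
  noise <- if (oor) ii[r] else ii[r & ii < meck]
  structure(list(meck_ma = meck, out_of_range = oor, responses = tab,
                 rejected_as_noise = noise),
            class = "mec_result")
}

#' @export
print.mec_result <- function(x, ...) {
  lab <- if (x$out_of_range) "OOR (out of measurement range)"
  else sprintf("%g mA", x$meck_ma)
  cat(sprintf("<mec_result> MEC_K = %s\n", lab))
  if (length(x$rejected_as_noise))
    cat("  rejected as noise:",
        paste(x$rejected_as_noise, collapse = ", "), "mA\n")
  invisible(x)
}

#' Run MEC_K detection over a session's K series and events
#'
#' Scores each stimulus with [evaluate_stimulus()] then applies
#' [detect_meck()].
#'
#' @param kseries a [k_series()].
#' @param events data frame with `onset_s`, `intensity_ma`, `duration_s`.
#' @inheritParams evaluate_stimulus
#' @inheritParams detect_meck
#' @return A `mec_result`.
#' @export
detect_meck_session <- function(kseries, events, pre_window_s = 10,
                                post_window_s = 20, threshold = 0.05,
                                anchor = c("offset", "onset"),
                                rule = c("suffix", "pairwise")) {
  anchor <- match.arg(anchor)
  rule <- match.arg(rule)
  ord <- order(events$intensity_ma)
  resp <- lapply(ord, function(j)
    evaluate_stimulus(kseries, events[j, , drop = FALSE],
                      pre_window_s = pre_window_s,
                      post_window_s = post_window_s,
                      threshold = threshold, anchor = anchor))
  detect_meck(resp, rule = rule)
}
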