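#' Rate of change in systolic blood pressure across skin incision
#'
#' The pre-incision systolic BP is the median of the last 10 beats strictly
#' before the incision; the post-incision systolic BP is the maximum over
#' the post-incision window `(incision, incision + post_window_s]`. ROC_BP
#' is reported as the percent change, `(post/pre - 1) * 100`; the raw ratio
#' is returned alongside.
#'
#' @param sbp_series data frame with columns `beat_time_s`, `sbp_mmhg`
#'   (per-beat systolic pressures).
#' @param incision_time_s time of the surgical skin incision (s).
#' @param post_window_s length of the post-incision window (s), default 120.
#' @param n_pre_beats number of pre-incision beats entering the median,
#'   default 10.
#' @return A `rocbp_result`: list with `pre_sbp_mmhg`, `post_sbp_mmhg`,
#'   `rocbp_pct`, `ratio`.
#' @export
compute_rocbp <- function(sbp_series, incision_time_s, post_window_s = 120,
                          n_pre_beats = 10) {
  stopifnot(is.data.frame(sbp_series),
            all(c("beat_time_s", "sbp_mmhg") %in% names(sbp_series)),
            post_window_s > 0)
  tt <- sbp_series$beat_time_s
  y <- sbp_series$sbp_mmhg
  pre <- which(tt < incision_time_s)
  if (length(pre) < n_pre_beats)
    stop(sprintf("need >= %d beats before the incision, found %d",
                 n_pre_beats, length(pre)))
  pre <- utils::tail(pre, n_pre_beats)
  post <- which(tt > incision_time_s & tt <= incision_time_s + post_window_s)
  if (length(post) == 0)
    stop("no beats in the post-incision window")
  pre_sbp <- median(y[pre])
  if (pre_sbp <= 0) stop("pre-incision sBP must be positive")
  post_sbp <- max(y[post])
  structure(list(pre_sbp_mmhg = pre_sbp, post_sbp_mmhg = post_sbp,
                 rocbp_pct = (post_sbp / pre_sbp - 1) * 100,
                 ratio = post_sbp / pre_sbp),
            class = "rocbp_result")
}

#' @export
print.rocbp_result <- function(x, ...) {
  cat(sprintf("<rocbp_result> pre %.1f mmHg, post %.1f mmHg, ROC_BP %.1f%%\n",
              x$pre_sbp_mmhg, x$post_sbp_mmhg, x$rocbp_pct))
  invisible(x)
}
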