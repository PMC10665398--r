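# Column schemas for the plain-text interchange formats. Every table is a
# headered CSV; MEC_K out-of-range is encoded as the literal token "OOR" in
# the meck_ma column.
.schemas <- list(
  waveform = c(time_s = "numeric", abp_mmhg = "numeric", ppg_pct = "numeric"),
  onsets   = c(onset_index = "integer"),
  events   = c(onset_s = "numeric", intensity_ma = "numeric",
               duration_s = "numeric"),
  kseries  = c(beat_time_s = "numeric", k = "numeric"),
  sbp      = c(beat_time_s = "numeric", sbp_mmhg = "numeric"),
  cohort   = c(subject_id = "character", meck_ma = "meck",
               rocbp_pct = "numeric")
)

#' Read a typed CSV table with schema validation
#'
#' Validates that every schema column is present and numerically parseable
#' (locale-independent, via [utils::read.csv()]); extra columns are kept
#' as-is. In the `cohort` schema the `meck_ma` column honours the literal
#' token `"OOR"` for out-of-range subjects, which becomes `NA` plus a
#' logical `out_of_range` column.
#'
#' @param path path to a CSV file.
#' @param schema one of `"waveform"`, `"onsets"`, `"events"`, `"kseries"`,
#'   `"sbp"`, `"cohort"`.
#' @return A data frame.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(.schemas))
    stop("unknown schema: ", schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  spec <- .schemas[[schema]]
  for (col in names(spec)) {
    if (!col %in% names(df))
      stop(sprintf("schema error: file %s is missing column '%s'",
                   path, col))
    if (spec[[col]] == "meck") {
      raw <- as.character(df[[col]])
      oor <- raw == "OOR"
      val <- suppressWarnings(as.numeric(raw))
      if (any(is.na(val) & !oor))
        stop(sprintf("schema error: column '%s' has values that are %s",
                     col, "neither numeric nor 'OOR'"))
      df[[col]] <- val
      df$out_of_range <- oor
    } else if (spec[[col]] != "character") {
      val <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(val) & !is.na(df[[col]])))
        stop(sprintf("schema error: column '%s' is not numeric", col))
      df[[col]] <- if (spec[[col]] == "integer") as.integer(val) else val
    }
  }
  df
}

#' Write a typed table as CSV
#'
#' Inverse of [read_table()]: in the `cohort` schema, out-of-range subjects
#' are written with the literal `OOR` token in `meck_ma` and the helper
#' `out_of_range` column is dropped.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param schema schema name (see [read_table()]).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema) {
  if (!schema %in% names(.schemas))
    stop("unknown schema: ", schema)
  if (schema == "cohort") {
    oor <- if ("out_of_range" %in% names(df)) df$out_of_range
    else is.na(df$meck_ma)
    df$meck_ma <- ifelse(oor, "OOR", as.character(df$meck_ma))
    df$out_of_range <- NULL
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file mirroring the arguments of
#'   [run_subject()] / [run_cohort()]: input paths plus a `params` block
#'   (`r2_min`, `threshold`, `pre_window_s`, `post_window_s`,
#'   `rocbp_post_window_s`, `rule`, `anchor`, `alpha`).
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.param <- function(params, name, default) {
  if (!is.null(params[[name]])) params[[name]] else default
}

#' Run the full single-subject pipeline
#'
#' Chains the per-subject stages: per-beat K estimation from the waveform
#' ([estimate_k_series()]), MEC_K detection from the stimulation events
#' ([detect_meck_session()]), and ROC_BP from the systolic-BP series
#' ([compute_rocbp()]). Inputs can be given as file paths (CSV, see
#' [read_table()]) or as in-memory objects. The K series driving MEC_K
#' detection is the one estimated from the waveform; alternatively a
#' precomputed `kseries` (e.g. from the bedside K monitor, or
#' [gen_session()]) can be supplied directly.
#'
#' Each stage error is re-raised with the stage name prefixed.
#'
#' @param waveform a [waveform_record()], or path to a waveform CSV (then
#'   `onsets` must be given); may be `NULL` when `kseries` is supplied.
#' @param onsets path to a beat-onset CSV (column `onset_index`), or an
#'   integer vector; ignored when `waveform` is already a record.
#' @param kseries optional precomputed [k_series()] (or path to a K CSV)
#'   used for MEC_K detection instead of the waveform estimate.
#' @param events data frame or path to a stimulation-events CSV; `NULL`
#'   skips the MEC_K stage.
#' @param sbp data frame or path to a per-beat systolic-BP CSV.
#' @param incision_time_s time of skin incision (s).
#' @param sample_rate_hz sampling rate for CSV waveform input (Hz).
#' @param params optional list of stage parameters (see
#'   [read_pipeline_config()]).
#' @return A `subject_report` list with `kseries`, `estimates`,
#'   `exclusions`, `mec` (NULL when no events), `rocbp`.
#' @export
run_subject <- function(waveform = NULL, onsets = NULL, kseries = NULL,
                        events = NULL, sbp, incision_time_s,
                        sample_rate_hz = 100, params = list()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  est <- NULL
  if (is.character(waveform)) {
    wtab <- stage("beat_mechanics", read_table(waveform, "waveform"))
    if (is.character(onsets))
      onsets <- stage("beat_mechanics", read_table(onsets, "onsets"))$onset_index
    if (is.null(onsets)) stop("beat onsets are required with a waveform CSV")
    waveform <- waveform_record(wtab$time_s, wtab$abp_mmhg, wtab$ppg_pct,
                                sample_rate_hz, onsets)
  }
  if (!is.null(waveform)) {
    est <- stage("beat_mechanics",
                 estimate_k_series(waveform,
                                   r2_min = .param(params, "r2_min", 0.95)))
  }
  if (is.character(kseries)) {
    ktab <- read_table(kseries, "kseries")
    kseries <- k_series(ktab$beat_time_s, ktab$k)
  }
  if (is.null(kseries)) {
    if (is.null(est)) stop("either a waveform or a kseries is required")
    kseries <- est$kseries
  }
  mec <- NULL
  if (!is.null(events)) {
    if (is.character(events)) events <- read_table(events, "events")
    mec <- stage("mec_detection", detect_meck_session(
      kseries, events,
      pre_window_s = .param(params, "pre_window_s", 10),
      post_window_s = .param(params, "post_window_s", 20),
      threshold = .param(params, "threshold", 0.05),
      anchor = .param(params, "anchor", "offset"),
      rule = .param(params, "rule", "suffix")))
  }
  if (is.character(sbp)) sbp <- read_table(sbp, "sbp")
  roc <- stage("rocbp", compute_rocbp(
    sbp, incision_time_s,
    post_window_s = .param(params, "rocbp_post_window_s", 120)))
  structure(list(kseries = kseries,
                 estimates = if (is.null(est)) NULL else est$estimates,
                 exclusions = if (is.null(est)) NULL
                 else attr(est$kseries, "exclusions"),
                 mec = mec, rocbp = roc),
            class = "subject_report")
}

#' Run the cohort-level analysis from a cohort table or CSV
#'
#' @param cohort a cohort data frame or path to a cohort CSV
#'   (`subject_id, meck_ma, rocbp_pct[, group]`, `OOR` token honoured).
#' @param external_equation optional list with `slope` and `intercept`.
#' @param alpha Grubbs significance level, default 0.05.
#' @param out_json optional path: when given, the result is also written as
#'   JSON (deterministic field order, fixed precision).
#' @return A `cohort_stats_result` (see [run_cohort_analysis()]).
#' @export
run_cohort <- function(cohort, external_equation = NULL, alpha = 0.05,
                       out_json = NULL) {
  if (is.character(cohort)) cohort <- read_table(cohort, "cohort")
  res <- run_cohort_analysis(cohort, external_equation = external_equation,
                             alpha = alpha)
  if (!is.null(out_json)) {
    payload <- list(
      n_total = res$n_total, n_analyzed = res$n_analyzed,
      r = round(res$r, 6), p_r = signif(res$p_r, 6),
      slope = round(res$slope, 6), intercept = round(res$intercept, 6),
      residual_sd = round(res$residual_sd, 6),
      grubbs_outliers = as.character(res$grubbs_outliers))
    if (!is.null(res$bland_altman))
      payload$bland_altman <- lapply(
        res$bland_altman[c("bias", "sd", "loa_low", "loa_high", "precision")],
        round, digits = 6)
    if (!is.null(res$parallel_lines))
      payload$parallel_lines <- list(
        p_slope_equality = signif(res$parallel_lines$p_slope_equality, 6),
        p_intercept_equality =
          signif(res$parallel_lines$p_intercept_equality, 6))
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}
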