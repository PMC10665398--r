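#' Configuration for a synthetic MEC_K / ROC_BP cohort
#'
#' Subjects' MEC_K thresholds are drawn from a discrete distribution over
#' the stimulus ladder (default mode at 30 mA with more than half the mass
#' on 20-40 mA, plus a small out-of-range probability), and measured ROC_BP
#' follows the linear law `ROC_BP = slope * MEC_K + intercept + e`,
#' `e ~ Normal(0, residual_sd^2)`. Default slope -0.27 %/mA and intercept
#' 28.81% match the generating regression used throughout the package;
#' default residual SD is 5%.
#'
#' Out-of-range subjects carry no MEC_K value and are excluded from any
#' MEC_K/ROC_BP pairing downstream; their measured ROC_BP is drawn about the
#' 80-mA prediction (they are weak responders).
#'
#' @param n_subjects number of subjects (>= 3).
#' @param slope linear slope, % per mA (default -0.27).
#' @param intercept intercept, % (default 28.81).
#' @param residual_sd residual standard deviation, % (default 5).
#' @param meck_distribution named probability vector over
#'   `c("10",...,"80","OOR")`; must sum to 1.
#' @param group_labels optional character vector of two labels; subjects are
#'   assigned to groups with probabilities `group_probs`.
#' @param group_probs length-2 probability vector (default `c(0.5, 0.5)`).
#' @param group_overrides optional named list mapping a group label to a
#'   list with `slope` and/or `intercept` overriding the global law.
#' @param seed integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects, slope = -0.27, intercept = 28.81,
                          residual_sd = 5,
                          meck_distribution = c("10" = 0.05, "20" = 0.15,
                                                "30" = 0.30, "40" = 0.15,
                                                "50" = 0.10, "60" = 0.08,
                                                "70" = 0.07, "80" = 0.05,
                                                "OOR" = 0.05),
                          group_labels = NULL, group_probs = c(0.5, 0.5),
                          group_overrides = NULL, seed = 1L) {
  if (n_subjects < 3)
    stop("n_subjects must be >= 3 (downstream statistics undefined)")
  stopifnot(residual_sd >= 0, all(meck_distribution >= 0))
  if (abs(sum(meck_distribution) - 1) > 1e-8)
    stop("meck_distribution must sum to 1")
  if (!is.null(group_labels) && length(group_labels) != 2)
    stop("group_labels must name exactly two groups")
  structure(list(n_subjects = as.integer(n_subjects), slope = slope,
                 intercept = intercept, residual_sd = residual_sd,
                 meck_distribution = meck_distribution,
                 group_labels = group_labels, group_probs = group_probs,
                 group_overrides = group_overrides, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort of subject records
#'
#' @param config a [cohort_config()].
#' @return A data frame of class `cohort` with columns `subject_id`,
#'   `meck_ma` (numeric, `NA` for out-of-range), `out_of_range` (logical),
#'   `rocbp_pct`, `group` (factor or `NA`).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  lev <- names(config$meck_distribution)
  draw <- sample(lev, n, replace = TRUE, prob = config$meck_distribution)
  oor <- draw == "OOR"
  meck <- suppressWarnings(as.numeric(draw))
  if (is.null(config$group_labels)) {
    grp <- rep(NA_character_, n)
  } else {
    grp <- sample(config$group_labels, n, replace = TRUE,
                  prob = config$group_probs)
  }
  slope <- rep(config$slope, n)
  intercept <- rep(config$intercept, n)
  for (g in names(config$group_overrides)) {
    ov <- config$group_overrides[[g]]
    hit <- !is.na(grp) & grp == g
    if (!is.null(ov$slope)) slope[hit] <- ov$slope
    if (!is.null(ov$intercept)) intercept[hit] <- ov$intercept
  }
  x <- ifelse(oor, 80, meck)  # OOR subjects respond like weak (80 mA) ones
  rocbp <- slope * x + intercept + rnorm(n, sd = config$residual_sd)
  structure(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       meck_ma = meck, out_of_range = oor,
                       rocbp_pct = rocbp, group = grp,
                       stringsAsFactors = FALSE),
            class = c("cohort", "data.frame"))
}
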