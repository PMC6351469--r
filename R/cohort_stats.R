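## Cohort-level inference: rank-sum comparison of postural scores between
## groups and Pearson correlation of the postural score with the attention
## subscore.

#' Wilcoxon rank-sum (Mann-Whitney) test between two independent samples
#'
#' Two-sided. The exact null distribution is used when both samples have at
#' most 10 observations and there are no ties; otherwise the normal
#' approximation with continuity correction is used and noted in `method`.
#'
#' @param a,b Numeric samples (non-empty).
#' @return A `rank_test_result` list: `statistic` (rank-sum W of `a`),
#'   `p_value`, `method` (`"exact"` or `"normal-approximation"`),
#'   `n1`, `n2`, `ties`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("samples must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal-approximation",
                 n1 = length(a), n2 = length(b), ties = ties),
            class = "rank_test_result")
}

#' Pearson correlation with t-based two-sided p-value
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return A `correlation_result` list: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("undefined correlation: constant input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

tukey_whiskers <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[2] + 1.5 * iqr])
  c(lower = lo, upper = hi)
}

#' Cohort report: group comparison and attention correlation
#'
#' Summarises postural scores per group (median and Tukey whiskers),
#' compares patients vs controls with the rank-sum test, and correlates the
#' patients' postural scores with their attention subscores (0-37).
#'
#' @param scores Data frame with `subject_id`, `score`.
#' @param clinical Data frame with `subject_id`, `group`
#'   (`"patient"`/`"control"`) and optionally `attention_subscore`.
#' @return A `cohort_report` list: `groups` (per-group n, median, whiskers),
#'   `rank_sum` test result, and `attention` correlation result (or `NULL`
#'   when no attention subscores are available).
#' @export
cohort_report <- function(scores, clinical) {
  d <- merge(scores, clinical, by = "subject_id")
  if (nrow(d) == 0) stopf("no subjects shared between scores and clinical")
  pat <- d$score[d$group == "patient"]
  ctl <- d$score[d$group == "control"]
  groups <- do.call(rbind, lapply(
    split(d$score, d$group),
    function(s) data.frame(n = length(s), median = median(s),
                           whisker_lower = tukey_whiskers(s)[1],
                           whisker_upper = tukey_whiskers(s)[2])))
  rank_sum <- if (length(pat) > 0 && length(ctl) > 0)
    wilcoxon_rank_sum(pat, ctl) else NULL
  attention <- NULL
  if ("attention_subscore" %in% names(d)) {
    dp <- d[d$group == "patient" & !is.na(d$attention_subscore), ]
    if (nrow(dp) >= 3 && sd(dp$score) > 0 && sd(dp$attention_subscore) > 0)
      attention <- pearson_correlation(dp$attention_subscore, dp$score)
  }
  structure(list(groups = groups, rank_sum = rank_sum,
                 attention = attention),
            class = "cohort_report")
}
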