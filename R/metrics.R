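#' Confusion matrix at a score cutoff
#'
#' A call is positive iff `score >= cutoff`, matching the classifier's
#' boundary convention (boundary scores go to the higher-risk class).
#'
#' @param pos_scores Scores of truly positive (diseased) sites.
#' @param neg_scores Scores of truly negative (normal) sites.
#' @param cutoff Decision cutoff.
#' @return One-row tibble with `TP`, `FP`, `TN`, `FN`, `cutoff`.
#' @export
#' @examples
#' confusion(c(3, 4), c(1, 2), 2.5)
confusion <- function(pos_scores, neg_scores, cutoff) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("both score lists must be non-empty", call. = FALSE)
  }
  tibble::tibble(
    TP = sum(pos_scores >= cutoff),
    FP = sum(neg_scores >= cutoff),
    TN = sum(neg_scores < cutoff),
    FN = sum(pos_scores < cutoff),
    cutoff = cutoff
  )
}

#' Diagnostic accuracy summary from a confusion matrix
#'
#' Sensitivity and specificity are reported as percentages, predictive
#' values as fractions (the conventional clinical-report mix). Division
#' guards return `NA` rather than erroring: PPV needs at least one
#' positive call, NPV at least one negative call. Raw values are returned;
#' display rounding (2 decimals for percentages, 3 for predictive values)
#' is left to [format_diagnostics()].
#'
#' @param cm One-row confusion tibble from [confusion()] (or any list with
#'   `TP`, `FP`, `TN`, `FN`).
#' @param auc Optional ROC-AUC to carry through into the summary.
#' @return One-row tibble: `sensitivity`, `specificity` (%), `ppv`, `npv`
#'   (fractions), `auc`, `cutoff`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' diagnostics(confusion(c(3, 4), c(1, 2), 2.5))
diagnostics <- function(cm, auc = NA_real_) {
  tp <- cm$TP; fp <- cm$FP; tn <- cm$TN; fn <- cm$FN
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative count", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("confusion matrix needs at least one positive and one negative",
         call. = FALSE)
  }
  tibble::tibble(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    auc = auc,
    cutoff = if (!is.null(cm$cutoff)) cm$cutoff else NA_real_,
    n_pos = tp + fn,
    n_neg = tn + fp
  )
}

#' @rdname diagnostics
#' @param summary A diagnostics tibble.
#' @export
format_diagnostics <- function(summary) {
  dplyr::mutate(
    summary,
    sensitivity = round(.data$sensitivity, 2),
    specificity = round(.data$specificity, 2),
    ppv = round(.data$ppv, 3),
    npv = round(.data$npv, 3),
    auc = round(.data$auc, 3)
  )
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' AUC is computed as the probability that a random positive outscores a
#' random negative, counting ties as half:
#' `(#{p > n} + 0.5 * #{p = n}) / (n_pos * n_neg)`. This equals the
#' trapezoidal area under the empirical ROC curve and is invariant under
#' any strictly increasing transform of the scores. Computed via midranks,
#' so it costs O((m+n) log(m+n)) rather than enumerating all pairs.
#'
#' @param pos_scores,neg_scores Non-empty score vectors.
#' @return AUC fraction in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(3, 4), c(1, 2))  # 1
roc_auc <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  if (n_pos == 0 || n_neg == 0) {
    stop("both score lists must be non-empty", call. = FALSE)
  }
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Distributional summary of one score class
#'
#' Quartiles use linear interpolation between order statistics (the
#' `p * (n - 1)` rule, [stats::quantile()] type 7). Scores above the Tukey
#' upper fence `Q3 + 1.5 * IQR` are counted as high outliers — lesions
#' whose ratio is extreme even for their class.
#'
#' @param scores Non-empty numeric vector.
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `iqr`, `min`, `max`,
#'   `n_above_upper_fence`.
#' @export
#' @examples
#' class_summary(c(1, 2, 3, 4, 5))
class_summary <- function(scores) {
  if (length(scores) == 0) stop("scores must be non-empty", call. = FALSE)
  q <- unname(quantile(scores, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  tibble::tibble(
    n = length(scores),
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    min = min(scores), max = max(scores),
    n_above_upper_fence = sum(scores > q[3] + 1.5 * iqr)
  )
}

#' Evaluate a cohort of labelled scores against a cutoff or model
#'
#' Splits records into positives and negatives by label, applies
#' [confusion()], [diagnostics()] and [roc_auc()] at the cutoff, and
#' summarises every class distribution with [class_summary()] — the full
#' diagnostic-ability report for one discrimination task (e.g. normal vs
#' OPML at the normal/suspect cutoff, or normal vs pooled abnormal).
#'
#' @param records Score-record tibble (see [read_score_table()]).
#' @param cutoff Numeric cutoff, or a `threshold_model` whose `t_opml` is
#'   used.
#' @param positive_labels Labels counted as positive (e.g. `"OPML"` or
#'   `c("OPML", "SCC")`).
#' @param negative_labels Labels counted as negative.
#' @return List with `diagnostics` (one-row tibble incl. AUC) and
#'   `class_summaries` (one row per label present).
#' @export
#' @examples
#' cohort <- generate_cohort(c(normal = 40, OPML = 40, SCC = 40), seed = 2)
#' evaluate_cohort(cohort, cutoff = 2.3, positive_labels = "OPML")$diagnostics
evaluate_cohort <- function(records, cutoff,
                            positive_labels = c("OPML", "SCC"),
                            negative_labels = "normal") {
  records <- validate_score_records(records)
  if (inherits(cutoff, "threshold_model")) cutoff <- cutoff$t_opml
  pos <- records$score[records$label %in% positive_labels]
  neg <- records$score[records$label %in% negative_labels]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("cohort lacks a class: needs >= 1 record in each of {",
         paste(positive_labels, collapse = ", "), "} and {",
         paste(negative_labels, collapse = ", "), "}", call. = FALSE)
  }
  cm <- confusion(pos, neg, cutoff)
  summaries <- records |>
    dplyr::group_by(label = .data$label) |>
    dplyr::reframe(class_summary(.data$score)) |>
    dplyr::arrange(factor(.data$label, levels = score_labels))
  list(
    diagnostics = diagnostics(cm, auc = roc_auc(pos, neg)),
    class_summaries = summaries
  )
}
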