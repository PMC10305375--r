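#' Confusion counts of a binary prediction
#'
#' A true positive is a formulation correctly predicted to form a
#' complex; a false positive a predicted complex that did not form; and
#' so on. The four counts partition the evaluated samples.
#'
#' @param y_true,y_pred Binary (0/1) vectors of equal length.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length.",
          class = "plc_error_length_mismatch")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort("y_true and y_pred must be binary (0/1).",
          class = "plc_error_label_levels")
  }
  tibble(tp = sum(y_true == 1 & y_pred == 1),
         fp = sum(y_true == 0 & y_pred == 1),
         tn = sum(y_true == 0 & y_pred == 0),
         fn = sum(y_true == 1 & y_pred == 0))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+FN+TN)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F1 score
#' `2 * precision * recall / (precision + recall)`. Zero-denominator
#' cases are reported as `NA` (an explicit "undefined" marker), never
#' silently as 0.
#'
#' @param counts A one-row tibble (or list) with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble with `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  prec <- safe_ratio(tp, tp + fp)
  rec <- safe_ratio(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  tibble(accuracy = safe_ratio(tp + tn, tp + fp + fn + tn),
         sensitivity = rec,
         specificity = safe_ratio(tn, tn + fp),
         precision = prec,
         f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' uniformly drawn positive sample outscores a uniformly drawn negative
#' one, with ties counted one half. Identical scores for all samples give
#' 0.5 (a random classifier); perfectly separating scores give 1.
#'
#' @param y_true Binary (0/1) labels; both classes must be present.
#' @param scores Real-valued scores (higher = more likely positive).
#' @return The AUC, a number in \[0, 1\].
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    abort("y_true and scores must have equal length.",
          class = "plc_error_length_mismatch")
  }
  if (!all(y_true %in% c(0, 1))) {
    abort("y_true must be binary (0/1).", class = "plc_error_label_levels")
  }
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to compute AUC.",
          class = "plc_error_single_class")
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric row for a set of predictions
#'
#' Convenience wrapper producing the standard report column set
#' (accuracy, AUC, specificity, sensitivity, F1, precision) from labels,
#' predicted labels and scores.
#'
#' @param y_true Binary truth.
#' @param y_pred Binary predictions.
#' @param scores Real-valued scores for the AUC (optional; AUC is `NA`
#'   when omitted or when only one class is present).
#' @return A one-row tibble.
#' @export
metric_row <- function(y_true, y_pred, scores = NULL) {
  m <- classification_metrics(confusion_counts(y_true, y_pred))
  auc <- NA_real_
  if (!is.null(scores) && length(unique(y_true)) == 2L) {
    auc <- roc_auc(y_true, scores)
  }
  dplyr::bind_cols(tibble(accuracy = m$accuracy, auc = auc),
                   m[c("specificity", "sensitivity", "f1", "precision")])
}
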