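# Classifier evaluation: ROC/AUC, Youden-index cutoff selection,
# reclassification and confusion-matrix metrics. The positive class is
# death (risk-score semantics) throughout.

#' ROC curve and area under it
#'
#' Sweeps every unique score (plus an upper sentinel) as a threshold with
#' the decision rule "predict death when score >= threshold", and computes
#' the area under the resulting curve by the trapezoidal rule. With tied
#' scores this equals the Mann-Whitney pairwise-concordance probability
#' with ties counted one half.
#'
#' @param scores numeric risk scores (higher = more likely death).
#' @param labels binary outcome, 1 = death (positive class).
#' @return object of class `roc_result`: list with `thresholds` (ascending),
#'   `tpr`, `fpr` (non-increasing in threshold), and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1 (1 = death)")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("ROC needs both classes present")
  }
  thr <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  # trapezoid over the curve from (0,0) [threshold Inf] to (1,1) [min score]
  ox <- rev(fpr)
  oy <- rev(tpr)
  auc <- sum(diff(ox) * (utils::head(oy, -1) + utils::tail(oy, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds; AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Youden-index cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 = TPR - FPR over the ROC
#' thresholds; ties are broken toward the smaller cutoff (the more
#' sensitive choice).
#'
#' @param roc a `roc_result`.
#' @return list with `cutoff` and `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  j <- roc$tpr - roc$fpr
  finite <- is.finite(roc$thresholds)
  jf <- j[finite]
  thrf <- roc$thresholds[finite]
  best <- which(jf == max(jf))
  pick <- best[which.min(thrf[best])]
  list(cutoff = thrf[pick], youden_j = jf[pick])
}

#' Threshold risk scores into class predictions
#'
#' Predicts death (1) when `score >= cutoff`; the boundary score counts as
#' death.
#'
#' @param scores numeric risk scores in `[0, 1]`.
#' @param cutoff decision cutoff (default 0.5).
#' @return integer vector of 0/1 predictions.
#' @export
classify_at <- function(scores, cutoff = 0.5) {
  as.integer(scores >= cutoff)
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, recall and F1 with death as the positive class.
#' When no positives are predicted, precision (and F1) are reported as 0
#' with `precision_defined = FALSE`.
#'
#' @param pred 0/1 predictions.
#' @param truth 0/1 outcomes (1 = death).
#' @return object of class `metrics_report`: list with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `precision`, `recall`, `f1`, `precision_defined`.
#' @export
classification_metrics <- function(pred, truth) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth)) stopf("pred and truth differ in length")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  tn <- sum(pred == 0L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  precision_defined <- (tp + fp) > 0L
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(pred),
         precision = precision, recall = recall, f1 = f1,
         precision_defined = precision_defined),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | precision %.4f%s | recall %.4f | F1 %.4f  (TP %d FP %d TN %d FN %d)\n",
    x$accuracy, x$precision, if (x$precision_defined) "" else " (no predicted positives)",
    x$recall, x$f1, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
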