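#' ROC analysis of a continuous score
#'
#' Builds the empirical ROC curve over all observed thresholds (prediction
#' rule: positive iff score >= threshold), computes the AUC by the
#' trapezoid rule — numerically identical to the Mann-Whitney U statistic
#' divided by n1*n0 — and returns the optimal cutoff maximizing the Youden
#' index J = sensitivity + specificity - 1, ties broken toward higher
#' specificity.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels two-class outcome (logical or factor; positive = second
#'   level / TRUE).
#' @return list with `roc` (data.frame threshold/fpr/tpr), `auc`, `cutoff`
#'   (a score value attaining the maximal J) and `youden`.
#' @export
roc_analysis <- function(scores, labels) {
  y <- as_binary_factor(labels)
  stop_if_not(length(scores) == length(y), "scores and labels differ in length")
  stop_if_not(all(is.finite(scores)), "scores must be finite")
  pos <- y == positive_level(y)
  n1 <- sum(pos); n0 <- sum(!pos)
  stop_if_not(n1 > 0 && n0 > 0, "both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1))
  fpr_full <- c(0, fpr); tpr_full <- c(0, tpr)
  auc <- sum(diff(fpr_full) * (tpr_full[-1] + tpr_full[-length(tpr_full)]) / 2)
  j <- tpr - fpr
  jmax <- max(j)
  # ties toward higher specificity = lower fpr = larger threshold,
  # i.e. the earliest index in the descending-threshold ordering
  opt <- which(j == jmax)[1]
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc, cutoff = thr[opt], youden = jmax)
}

#' Confusion counts at a score cutoff
#'
#' Predicts positive iff `score >= cutoff` and tabulates the result against
#' the labels.
#'
#' @param scores numeric scores.
#' @param labels two-class outcome.
#' @param cutoff finite decision threshold.
#' @return a `confusion_summary`: TP, TN, FP, FN, n, accuracy, the cutoff
#'   used, and the AUC of the scores.
#' @export
confusion <- function(scores, labels, cutoff) {
  stop_if_not(is.finite(cutoff), "cutoff must be finite")
  y <- as_binary_factor(labels)
  pos <- y == positive_level(y)
  pred <- scores >= cutoff
  res <- confusion_summary(tp = sum(pred & pos), tn = sum(!pred & !pos),
                           fp = sum(pred & !pos), fn = sum(!pred & pos),
                           cutoff = cutoff)
  res$auc <- roc_analysis(scores, labels)$auc
  res
}

#' @rdname confusion
#' @param tp,tn,fp,fn confusion counts (e.g. from a published performance
#'   table); accuracy is `(TP + TN) / n`.
#' @param auc optional AUC to carry along.
#' @export
confusion_summary <- function(tp, tn, fp, fn, cutoff = NA_real_,
                              auc = NA_real_) {
  stop_if_not(all(c(tp, tn, fp, fn) >= 0), "counts must be non-negative")
  n <- tp + tn + fp + fn
  stop_if_not(n > 0, "empty confusion table")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
                 accuracy = (tp + tn) / n, cutoff = cutoff, auc = auc),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  TN %d  FP %d  FN %d | accuracy %.1f%%%s\n",
              x$tp, x$tn, x$fp, x$fn, 100 * x$accuracy,
              if (is.finite(x$auc)) sprintf("  AUC %.2f", x$auc) else ""))
  invisible(x)
}
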