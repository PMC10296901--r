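#' Precision and recall at a threshold
#'
#' Prediction rule: `score >= threshold` predicts a positive. When no
#' positives are predicted, precision is reported as 1 by the usual
#' precision-recall-curve convention (it only affects the curve endpoint).
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (1 = true link), same length as `scores`.
#' @param threshold Decision threshold.
#' @return A list with `precision` and `recall`.
#' @export
precision_recall <- function(scores, labels, threshold) {
  check_scored(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  list(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Average precision
#'
#' The step-sum \eqn{AP = \sum_n (R_n - R_{n-1}) P_n} taken over the ranked
#' prediction list, evaluated at each distinct score (tied scores enter as a
#' single operating point, making the value invariant to the order of ties).
#' No interpolation is applied.
#'
#' @inheritParams precision_recall
#' @return AP in (0, 1].
#' @export
average_precision <- function(scores, labels) {
  check_scored(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop_validation("average precision needs >= 1 positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  # last index of each tied block = the operating point for that threshold
  last <- which(!duplicated(s, fromLast = TRUE))
  tp_k <- tp[last]
  prec <- tp_k / last
  rec <- tp_k / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' ROC curve
#'
#' One operating point per distinct score (ties collapse), thresholded as
#' `score >= t`, plus the (0, 0) origin whose nominal threshold is `Inf`.
#' The final point is always (1, 1).
#'
#' @inheritParams precision_recall
#' @return An object of class `roc_points`: list with descending `thresholds`
#'   and aligned `tpr`, `fpr` vectors.
#' @export
roc_curve <- function(scores, labels) {
  check_scored(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_validation("ROC needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  structure(
    list(thresholds = c(Inf, s[last]),
         tpr = c(0, tp / n_pos),
         fpr = c(0, fp / n_neg)),
    class = "roc_points"
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()], equal to the Mann-Whitney pair
#' statistic: the probability that a random positive outscores a random
#' negative, with tied pairs credited 1/2.
#'
#' @param scores Either a numeric score vector or a `roc_points` object.
#' @param labels Binary labels (ignored when `scores` is already a curve).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels = NULL) {
  curve <- if (inherits(scores, "roc_points")) scores
           else roc_curve(scores, labels)
  k <- length(curve$fpr)
  sum(diff(curve$fpr) * (curve$tpr[-1L] + curve$tpr[-k]) / 2)
}

#' Best threshold by Youden's J
#'
#' J = sensitivity + specificity - 1 = TPR - FPR, evaluated at every ROC
#' operating point; the maximizing point gives the best threshold. Ties in J
#' are broken toward the higher (more conservative) threshold. The (0, 0)
#' origin never wins: its J of 0 is also attained at (1, 1), which carries a
#' finite threshold.
#'
#' @param scores Score vector or `roc_points`.
#' @param labels Binary labels (ignored for a curve input).
#' @return A list with `threshold` and `J`.
#' @export
youden_best_threshold <- function(scores, labels = NULL) {
  curve <- if (inherits(scores, "roc_points")) scores
           else roc_curve(scores, labels)
  finite <- is.finite(curve$thresholds)
  j <- curve$tpr[finite] - curve$fpr[finite]
  thr <- curve$thresholds[finite]
  best_j <- max(j)
  # thresholds descend, so the first maximizer is the highest threshold
  k <- which(j == best_j)[1L]
  list(threshold = thr[k], J = best_j)
}

#' Metrics report for a scored evaluation set
#'
#' @inheritParams precision_recall
#' @return A list with `auc`, `ap`, `best_threshold`, `J`.
#' @export
metrics_report <- function(scores, labels) {
  curve <- roc_curve(scores, labels)
  best <- youden_best_threshold(curve)
  list(auc = auc(curve), ap = average_precision(scores, labels),
       best_threshold = best$threshold, J = best$J)
}

check_scored <- function(scores, labels) {
  if (length(scores) == 0L) stop_validation("empty score vector")
  if (length(scores) != length(labels)) {
    stop_validation("scores and labels differ in length")
  }
  if (!all(labels %in% c(0, 1))) {
    stop_validation("labels must be binary (0/1)")
  }
  invisible(TRUE)
}
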