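# Evaluation metrics for binary localization calls
# (positive class = cytoplasm).

#' Confusion counts
#'
#' @param y_true binary 0/1 truth (1 = cytoplasm).
#' @param y_pred binary 0/1 predicted labels.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  list(TP = sum(y_true == 1 & y_pred == 1),
       FP = sum(y_true == 0 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FN = sum(y_true == 1 & y_pred == 0))
}

# 0-on-zero-denominator convention, with a warning
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator, reporting 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Threshold metrics from confusion counts
#'
#' Recall, precision, specificity, accuracy, F1 and MCC. Any zero denominator
#' yields 0 with a warning (including an MCC denominator of 0).
#'
#' @param cc list from [confusion_counts()].
#' @return named list of the six scalar metrics.
#' @export
scalar_metrics <- function(cc) {
  TP <- as.double(cc$TP); FP <- as.double(cc$FP)
  TN <- as.double(cc$TN); FN <- as.double(cc$FN)
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(
    recall = safe_ratio(TP, TP + FN, "recall"),
    precision = safe_ratio(TP, TP + FP, "precision"),
    specificity = safe_ratio(TN, TN + FP, "specificity"),
    accuracy = safe_ratio(TP + TN, TP + FP + TN + FN, "accuracy"),
    f1 = safe_ratio(2 * TP, 2 * TP + FP + FN, "f1"),
    mcc = safe_ratio(TP * TN - FP * FN, mcc_den, "mcc")
  )
}

#' ROC/PR curves, AUC and average precision
#'
#' AUC is the trapezoidal integral of TPR over FPR across all distinct score
#' thresholds (tied scores are grouped); AP is the step-wise (non-
#' interpolated) precision-recall integral `sum (R_i - R_{i-1}) * P_i`.
#'
#' @param y_true binary 0/1 truth containing both classes.
#' @param y_prob finite numeric scores (higher = more cytoplasmic).
#' @return list with `auc`, `ap`, `roc_points` (fpr, tpr, threshold) and
#'   `pr_points` (recall, precision, threshold).
#' @export
curve_metrics <- function(y_true, y_prob) {
  if (length(y_true) != length(y_prob)) stop("length mismatch")
  if (any(!is.finite(y_prob))) stop("scores must be finite")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: y_true contains a single class")
  }
  ord <- order(y_prob, decreasing = TRUE)
  yt <- y_true[ord]
  sc <- y_prob[ord]
  grp_end <- which(c(sc[-1] != sc[-length(sc)], TRUE))  # last index per tie group
  tp <- cumsum(yt)[grp_end]
  fp <- cumsum(1 - yt)[grp_end]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  prec <- tp / (tp + fp)
  auc <- sum(diff(c(0, fpr)) * (tpr + c(0, utils::head(tpr, -1L)))) / 2
  ap <- sum(diff(c(0, tpr)) * prec)
  list(auc = auc, ap = ap,
       roc_points = data.frame(threshold = c(Inf, sc[grp_end]),
                               fpr = c(0, fpr), tpr = c(0, tpr)),
       pr_points = data.frame(threshold = sc[grp_end],
                              recall = tpr, precision = prec))
}

#' Full metrics report from scores
#'
#' Thresholds the scores at `threshold` for the confusion-based metrics and
#' adds AUC/AP from [curve_metrics()].
#'
#' @param y_true binary 0/1 truth.
#' @param y_prob numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return named list: recall, precision, specificity, accuracy, f1, mcc,
#'   auc, ap, plus `confusion` and the curve point tables.
#' @export
evaluate_predictions <- function(y_true, y_prob, threshold = 0.5) {
  cc <- confusion_counts(y_true, as.integer(y_prob >= threshold))
  out <- scalar_metrics(cc)
  cur <- curve_metrics(y_true, y_prob)
  out$auc <- cur$auc
  out$ap <- cur$ap
  out$confusion <- cc
  out$roc_points <- cur$roc_points
  out$pr_points <- cur$pr_points
  out
}
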