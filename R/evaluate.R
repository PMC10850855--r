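# Validation of the curation classifier: ROC/AUC by threshold sweep,
# confusion-matrix metrics, and per-feature bias ratios between manually
# and model-curated datasets.

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the score values, recording the
#' false-positive and true-positive rates; the area under the curve is
#' computed by trapezoidal integration. AUC 1 is a perfect ranking, 0.5
#' chance level.
#'
#' @param truth 0/1 labels (1 = good detection); both classes required.
#' @param scores Continuous decision scores, higher = more likely good.
#' @return List with `points` (tibble: threshold, fpr, tpr) and `auc`.
#' @export
roc_curve_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores)) stop_validation("truth and scores differ in length")
  P <- sum(truth == 1L); N <- sum(truth == 0L)
  if (P == 0L || N == 0L) stop_validation("ROC needs both classes in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(truth[ord] == 1L)
  fp <- cumsum(truth[ord] == 0L)
  # collapse tied scores: keep the last index of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  points <- tibble::tibble(threshold = c(Inf, s[last]),
                           fpr = c(0, fp[last] / N),
                           tpr = c(0, tp[last] / P))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Confusion matrix and derived performance metrics
#'
#' Positive class is 1 (good detection). Metrics with a zero denominator
#' are reported as missing with a warning. False positives deserve
#' particular attention in this application: they are incorrect detections
#' that would slip into downstream analysis.
#'
#' @param truth,predicted Equal-length 0/1 label vectors.
#' @return List with `counts` (TP, FP, TN, FN) and `metrics` (accuracy,
#'   precision, recall, specificity, f1).
#' @export
confusion_report <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_validation("truth and predicted differ in length")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fn <- sum(truth == 1L & predicted == 0L)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); reported as NA", what))
      return(NA_real_)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) {
      warn("F1 undefined (precision + recall = 0); reported as NA")
    }
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       metrics = c(accuracy = (tp + tn) / length(truth),
                   precision = precision, recall = recall,
                   specificity = safe_div(tn, tn + fp, "specificity"),
                   f1 = f1))
}

#' Per-feature bias ratios of model curation vs manual curation
#'
#' For each feature, the ratio of its mean over model-kept rows to its
#' mean over manually-kept rows. A ratio deviating from 1 beyond the
#' tolerance flags a curation bias for that feature.
#'
#' @param features Feature table (26 feature columns).
#' @param manual_keep,model_keep Logical masks over the rows (cells kept
#'   by the manual and by the model curation).
#' @param tolerance Relative deviation from 1 above which a feature is
#'   flagged (default 0.05).
#' @return Tibble with `feature`, `ratio`, `flagged`.
#' @export
bias_ratios <- function(features, manual_keep, model_keep, tolerance = 0.05) {
  if (!any(manual_keep) || !any(model_keep)) {
    stop_validation("both keep masks must select at least one row")
  }
  df <- as.data.frame(features)[, feature_names(), drop = FALSE]
  ratios <- vapply(feature_names(), function(fn) {
    manual_mean <- mean(df[[fn]][manual_keep], na.rm = TRUE)
    model_mean <- mean(df[[fn]][model_keep], na.rm = TRUE)
    if (!is.finite(manual_mean) || abs(manual_mean) < 1e-300) {
      warn(sprintf("manual mean of %s is zero; bias ratio undefined", fn))
      return(NA_real_)
    }
    model_mean / manual_mean
  }, numeric(1))
  tibble::tibble(feature = feature_names(), ratio = unname(ratios),
                 flagged = !is.na(ratios) & abs(ratios - 1) > tolerance)
}
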