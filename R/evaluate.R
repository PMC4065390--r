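# Scoring detectors against ground truth. The evaluation unit is the
# calendar date: a true positive is a truly contaminated date that was
# flagged.

#' Confusion counts of flags against truth
#'
#' @param flags Logical vector: date flagged by a detector.
#' @param truth Logical vector: date truly contaminated.
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn` (their sum is the number
#'   of dates).
#' @export
confusion_counts <- function(flags, truth) {
  flags <- as.logical(flags); truth <- as.logical(truth)
  if (length(flags) != length(truth)) {
    bg_abort("`flags` and `truth` must have equal length.",
             "birthgam_data_error")
  }
  if (anyNA(flags) || anyNA(truth)) {
    bg_abort("`flags`/`truth` must not contain NA.", "birthgam_data_error")
  }
  tibble(
    tp = sum(flags & truth), fp = sum(flags & !truth),
    fn = sum(!flags & truth), tn = sum(!flags & !truth)
  )
}

#' Derived detection metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and false negative rate `fn/(tp+fn)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0. Values
#' are stored at full precision; the print method shows 4 decimals.
#'
#' @param conf A confusion tibble (or anything with `tp`, `fp`, `fn`, `tn`),
#'   e.g. from [confusion_counts()].
#' @return A one-row tibble of class `eval_result` with the counts and the
#'   four ratios.
#' @examples
#' detection_metrics(tibble::tibble(tp = 51, fp = 8, fn = 7, tn = 44000))
#' @export
detection_metrics <- function(conf) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble(
    tp = conf$tp, fp = conf$fp, fn = conf$fn, tn = conf$tn,
    sensitivity = ratio(conf$tp, conf$tp + conf$fn),
    specificity = ratio(conf$tn, conf$tn + conf$fp),
    ppv = ratio(conf$tp, conf$tp + conf$fp),
    fnr = ratio(conf$fn, conf$tp + conf$fn)
  )
  class(out) <- unique(c("eval_result", class(out)))
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("sensitivity %s  specificity %s  ppv %s  fnr %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$fnr)))
  invisible(x)
}

#' ROC curve and AUC by the rank (Mann-Whitney) statistic
#'
#' Higher scores mean more anomalous. The AUC is the tie-corrected
#' Mann-Whitney statistic (average ranks give tied pairs half credit, which
#' equals the trapezoidal area under the empirical ROC); the curve is
#' obtained by sweeping the unique score thresholds.
#'
#' @param scores Real anomaly score per date.
#' @param truth Logical vector: date truly contaminated. Both classes must
#'   be present.
#' @return A list with `auc` and `curve` (tibble `threshold`, `tpr`, `fpr`).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) {
    bg_abort("`scores` and `truth` must have equal length.",
             "birthgam_data_error")
  }
  if (anyNA(scores) || anyNA(truth)) {
    bg_abort("`scores`/`truth` must not contain NA.", "birthgam_data_error")
  }
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) {
    bg_abort("ROC needs at least one positive and one negative.",
             "birthgam_data_error")
  }
  r <- rank(scores)                       # average ranks: ties half credit
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  st <- truth[ord]
  cum_tp <- cumsum(st); cum_fp <- cumsum(!st)
  # last index of each run of equal scores along the sorted order
  m <- length(s_sorted)
  idx <- which(c(s_sorted[-1] != s_sorted[-m], TRUE))
  curve <- tibble(
    threshold = c(Inf, s_sorted[idx]),
    tpr = c(0, cum_tp[idx] / n1),
    fpr = c(0, cum_fp[idx] / n0)
  )
  list(auc = auc, curve = curve)
}
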