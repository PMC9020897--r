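#' Confusion matrix from probabilities
#'
#' Thresholds predicted probabilities (positive iff `prob >= threshold`)
#' and cross-tabulates against the true labels into TP / FN / FP / TN
#' counts.
#'
#' @param y_true Binary ground-truth vector.
#' @param y_prob Predicted probabilities in \[0, 1\], same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_matrix` list with fields `tp`, `fn`, `fp`, `tn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
#' @export
confusion <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop("`y_true` and `y_prob` lengths differ", call. = FALSE)
  }
  if (any(y_prob < 0 | y_prob > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(y_prob >= threshold)
  structure(list(
    tp = sum(y_true == 1 & pred == 1),
    fn = sum(y_true == 1 & pred == 0),
    fp = sum(y_true == 0 & pred == 1),
    tn = sum(y_true == 0 & pred == 0)
  ), class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

.safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Classification metric suite
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1 (harmonic mean of
#' precision and recall). Any 0/0 ratio is reported as 0 and flagged in
#' the `degenerate` column.
#'
#' @param cm A [confusion()] matrix.
#' @return One-row tibble: `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`, `degenerate` (comma-separated names of 0/0
#'   metrics, or `NA`).
#' @export
classification_metrics <- function(cm) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  degenerate <- character()
  if (cm$tp + cm$fp == 0) degenerate <- c(degenerate, "precision")
  if (cm$tp + cm$fn == 0) degenerate <- c(degenerate, "recall")
  if (cm$tn + cm$fp == 0) degenerate <- c(degenerate, "specificity")
  precision <- .safe_ratio(cm$tp, cm$tp + cm$fp)
  recall <- .safe_ratio(cm$tp, cm$tp + cm$fn)
  f1 <- .safe_ratio(2 * precision * recall, precision + recall)
  if (precision + recall == 0) degenerate <- c(degenerate, "f1")
  tibble::tibble(
    accuracy = (cm$tp + cm$tn) / total,
    precision = precision,
    recall = recall,
    specificity = .safe_ratio(cm$tn, cm$tn + cm$fp),
    f1 = f1,
    degenerate = if (length(degenerate)) {
      paste(degenerate, collapse = ",")
    } else {
      NA_character_
    }
  )
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' balanced statistic in \[-1, 1\] that only rewards classifiers correct
#' on both classes; defined as 0 when any denominator factor vanishes.
#'
#' @param cm A [confusion()] matrix.
#' @return The MCC value.
#' @export
mcc <- function(cm) {
  den <- (cm$tp + cm$fp) * (cm$tp + cm$fn) *
    (cm$tn + cm$fp) * (cm$tn + cm$fn)
  if (den == 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(den)
}

#' Full metric report
#'
#' The Table-style report used across the package: the five
#' classification metrics plus MCC, as one tibble row.
#'
#' @inheritParams classification_metrics
#' @return One-row tibble with `accuracy`, `precision`, `recall`, `f1`,
#'   `specificity`, `mcc`.
#' @export
metric_report <- function(cm) {
  m <- classification_metrics(cm)
  tibble::tibble(
    accuracy = m$accuracy, precision = m$precision, recall = m$recall,
    f1 = m$f1, specificity = m$specificity, mcc = mcc(cm)
  )
}
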