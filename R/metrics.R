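#' Confusion-matrix metric suite
#'
#' The five standard binary-classification metrics: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (undefined); the
#' others are still returned.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (at least one positive).
#' @return One-row tibble with `accu`, `sen`, `spec`, `prec`, `mcc`.
#' @export
#' @examples
#' compute_metrics(tp = 90, tn = 80, fp = 20, fn = 10)
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || sum(counts) < 1) {
    stop_dtiforge("confusion counts must be non-negative with positive total",
                  "dtiforge_input_error")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  tibble(
    accu = (tp + tn) / sum(counts),
    sen  = safe_div(tp, tp + fn),
    spec = safe_div(tn, tn + fp),
    prec = safe_div(tp, tp + fp),
    mcc  = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  )
}

confusion_counts <- function(truth, predicted) {
  list(tp = sum(truth == 1 & predicted == 1),
       tn = sum(truth == 0 & predicted == 0),
       fp = sum(truth == 0 & predicted == 1),
       fn = sum(truth == 1 & predicted == 0))
}

#' ROC curve and AUC
#'
#' Sweeps a threshold over the distinct score values (tied scores collapse
#' into a single step), accumulating sensitivity and 1-specificity, and
#' integrates by the trapezoidal rule.  The grouped-threshold trapezoid is
#' equivalent to giving half credit to ties, so the AUC equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores Numeric decision scores, larger meaning more positive.
#' @param labels Binary truth labels (0/1); both classes must be present.
#' @return An object of class `dti_roc`: list with `points` (tibble of
#'   `fpr`, `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_dtiforge("AUC undefined: only one class present",
                  "dtiforge_undefined_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  step_end <- c(which(diff(s) != 0), length(s))   # last index of each tie group
  tp <- cumsum(y)[step_end]
  fp <- step_end - tp
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = tibble(fpr = fpr, tpr = tpr), auc = auc),
            class = "dti_roc")
}

#' @export
print.dti_roc <- function(x, ...) {
  cat(sprintf("<dti_roc> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @rdname roc_curve
#' @param x A `dti_roc`.
#' @param ... Unused.
#' @export
tidy.dti_roc <- function(x, ...) x$points

#' @rdname roc_curve
#' @param object A `dti_roc`.
#' @export
autoplot.dti_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal()
}

#' Metrics for scored predictions
#'
#' Convenience wrapper: thresholds the continuous score at 0 for the
#' confusion counts, computes the metric suite and appends the trapezoidal
#' AUC.
#'
#' @param scores Continuous decision scores.
#' @param labels Binary truth labels.
#' @return One-row tibble `accu`, `sen`, `spec`, `prec`, `mcc`, `auc`.
#' @export
score_metrics <- function(scores, labels) {
  cc <- confusion_counts(labels, as.integer(scores > 0))
  dplyr::bind_cols(do.call(compute_metrics, cc),
                   tibble(auc = roc_curve(scores, labels)$auc))
}
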