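# Confusion-matrix performance metrics and the scalarized wrapper fitness.
#
# Accuracy   = (TP + TN) / (TP + TN + FP + FN)
# Jc         = (TP + TN) / ((A + P) - (TP + TN))   with A, P the numbers of
#              actual and predicted instances (both equal the evaluation-set
#              size in standard use, giving Jc = Acc / (2 - Acc))
# F1         = 2 TP / (2 TP + FP + FN)
# Sens./Spec.= TP / (TP + FN),  TN / (TN + FP)
# FDR        = 1 - selected/total   (feature decreasing rate, the
#              feature-reduction objective -- not false discovery rate)
# fitness    = w_accuracy * accuracy + w_fdr * FDR

#' Confusion counts from binary label vectors
#'
#' @param y_true,y_pred binary vectors (`0`/`1`) of equal length >= 1.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop_ssfs("y_true and y_pred must have equal length >= 1",
              class = "metric_error")
  }
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop_ssfs("labels must be binary (0/1)", class = "metric_error")
  }
  confusion_counts(
    tp = sum(y_true == 1L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fp = sum(y_true == 0L & y_pred == 1L),
    fn = sum(y_true == 1L & y_pred == 0L)
  )
}

#' @rdname confusion
#' @param tp,tn,fp,fn non-negative integer counts (at least one positive).
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || sum(counts) < 1) {
    stop_ssfs("confusion counts must be non-negative with a positive total",
              class = "metric_error")
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' The Jaccard variant uses the numbers of actual (`n_actual`) and predicted
#' (`n_predicted`) instances explicitly; in standard use both equal the
#' evaluation-set size `tp + tn + fp + fn`.
#'
#' @param cm a [confusion_counts()].
#' @param n_actual,n_predicted instance counts `A` and `P` of the Jaccard
#'   denominator; default to the confusion total.
#' @return An object of class `metric_report` with fields `accuracy`,
#'   `jaccard`, `f1`, `sensitivity`, `specificity`.  A zero denominator in
#'   any metric raises a `degenerate_metric_error` rather than returning 0.
#' @export
classification_metrics <- function(cm, n_actual = NULL, n_predicted = NULL) {
  stopifnot(inherits(cm, "confusion_counts"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  n_actual <- n_actual %||% total
  n_predicted <- n_predicted %||% total
  correct <- cm$tp + cm$tn
  dens <- c(total = total,
            jaccard = (n_actual + n_predicted) - correct,
            f1 = 2 * cm$tp + cm$fp + cm$fn,
            sensitivity = cm$tp + cm$fn,
            specificity = cm$tn + cm$fp)
  if (any(dens == 0)) {
    stop_ssfs("degenerate metric denominator(s): %s",
              paste(names(dens)[dens == 0], collapse = ", "),
              class = "degenerate_metric_error")
  }
  structure(list(
    accuracy = correct / total,
    jaccard = correct / dens[["jaccard"]],
    f1 = 2 * cm$tp / dens[["f1"]],
    sensitivity = cm$tp / dens[["sensitivity"]],
    specificity = cm$tn / dens[["specificity"]]
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report acc=%.4f jc=%.4f f1=%.4f sens=%.4f spec=%.4f>\n",
    x$accuracy, x$jaccard, x$f1, x$sensitivity, x$specificity))
  invisible(x)
}

#' Serialize a metric report as a benchmark-table row
#'
#' Column order matches the comparison tables of the field: NSF (number of
#' selected features), FDR, Accuracy, JC, F1, Sens., Spec.
#'
#' @param report a `metric_report`.
#' @param nsf number of selected features.
#' @param n_total total number of features.
#' @param method method label for the row.
#' @return A one-row `data.frame`.
#' @export
metric_row <- function(report, nsf, n_total, method = "method") {
  stopifnot(inherits(report, "metric_report"))
  data.frame(
    Method = method, NSF = as.integer(nsf),
    FDR = feature_decreasing_rate(nsf, n_total),
    Accuracy = report$accuracy, JC = report$jaccard, F1 = report$f1,
    Sens. = report$sensitivity, Spec. = report$specificity,
    check.names = FALSE
  )
}

#' Feature decreasing rate
#'
#' `FDR = 1 - n_selected / n_total`: the feature-reduction objective (1 when
#' no feature is kept, 0 when all are).
#'
#' @param n_selected number of selected features, `0 <= n_selected <=
#'   n_total`.
#' @param n_total total number of features (>= 1).
#' @return A value in `[0, 1]`.
#' @export
feature_decreasing_rate <- function(n_selected, n_total) {
  if (n_total < 1 || n_selected < 0 || n_selected > n_total) {
    stop_ssfs("require 0 <= n_selected <= n_total, n_total >= 1",
              class = "metric_error")
  }
  1 - n_selected / n_total
}

#' Scalarized two-objective fitness
#'
#' The weighted sum of the classification accuracy and the feature
#' decreasing rate, maximized by the selection metaheuristics.
#'
#' @param accuracy classification accuracy in `[0, 1]`.
#' @param fdr feature decreasing rate in `[0, 1]`.
#' @param weights a [fitness_weights()] (default 0.90 / 0.10).
#' @return `w_accuracy * accuracy + w_fdr * fdr`, in `[0, 1]`.
#' @export
fitness_score <- function(accuracy, fdr, weights = fitness_weights()) {
  stopifnot(inherits(weights, "fitness_weights"))
  if (accuracy < 0 || accuracy > 1 || fdr < 0 || fdr > 1) {
    stop_ssfs("accuracy and fdr must lie in [0, 1]", class = "metric_error")
  }
  weights$w_accuracy * accuracy + weights$w_fdr * fdr
}
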