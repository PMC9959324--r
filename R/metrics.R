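#' Confusion counts from label vectors
#'
#' Tallies TP/TN/FP/FN with the unhealthy (tumor) class as positive.
#'
#' @param y_true,y_pred Equal-length vectors of `"healthy"`/`"unhealthy"`
#'   labels.
#' @param positive The positive-class label.
#' @return An object of class `confusion_counts`.
#' @export
confusion_from_labels <- function(y_true, y_pred, positive = "unhealthy") {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    hsi_abort("label vectors must be non-empty and of equal length",
              "input_error")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  confusion_counts(tp, tn, fp, fn)
}

confusion_signed <- function(y_true, y_pred) {
  confusion_counts(sum(y_true == 1 & y_pred == 1),
                   sum(y_true == -1 & y_pred == -1),
                   sum(y_true == -1 & y_pred == 1),
                   sum(y_true == 1 & y_pred == -1))
}

#' Confusion-count container
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  if (any(counts < 0)) hsi_abort("counts must be non-negative", "input_error")
  structure(as.list(counts), class = "confusion_counts")
}

#' Imbalance-aware classification metrics
#'
#' Computes accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient from a confusion matrix. MCC is the headline metric here: it
#' stays near 0 for any trivial classifier on an imbalanced set, where
#' accuracy/precision/recall can all look excellent. Degenerate
#' denominators follow the standard conventions: precision/recall/F1 are 0
#' when their denominators are 0, and MCC is 0 when any factor under its
#' square root vanishes.
#'
#' @param c A [confusion_counts()].
#' @return An object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1` (the harmonic mean of the reported
#'   precision and recall), and `mcc` in \[-1, 1\].
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$TP); tn <- as.numeric(c$TN)
  fp <- as.numeric(c$FP); fn <- as.numeric(c$FN)
  n <- tp + tn + fp + fn
  if (n == 0) hsi_abort("empty confusion matrix", "input_error")
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, mcc = mcc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  MCC %.3f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' Serialize a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
metrics_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Append a result row to a CSV results table
#'
#' One row per experiment configuration, mirroring the layout
#' (configuration columns, then accuracy/precision/recall/F1/MCC).
#'
#' @param config Named list/one-row data frame describing the
#'   configuration (loss, gamma, alpha, variant, patch size, ...).
#' @param report A `metrics_report`.
#' @param path CSV path; created with a header if absent.
#' @return The appended row, invisibly.
#' @export
append_results_csv <- function(config, report, path) {
  row <- cbind(as.data.frame(config, stringsAsFactors = FALSE),
               as.data.frame(unclass(report)))
  if (!file.exists(path)) {
    write.csv(row, path, row.names = FALSE)
  } else {
    existing <- read.csv(path, stringsAsFactors = FALSE)
    write.csv(rbind(existing, row), path, row.names = FALSE)
  }
  invisible(row)
}
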