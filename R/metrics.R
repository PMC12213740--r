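# Support-weighted evaluation metrics and confusion matrix.

#' Classification metrics with support weighting
#'
#' Builds the K x K confusion matrix (rows = truth, columns = prediction)
#' and per-class precision/recall/F1. The headline metrics are
#' support-weighted: `w_f1 = sum_c (n_c/N) F1_c` and
#' `w_acc = sum_c (n_c/N) recall_c`. Weighting recall by class supports
#' makes w_acc algebraically identical to plain accuracy.
#'
#' @param truth integer vector of true class indices (1-based).
#' @param predicted integer vector of predicted class indices.
#' @param labels character vector of class names (length K).
#' @return A `tf_metrics` list: `confusion`, `per_class` (data.frame),
#'   `w_acc`, `w_f1`, `n`.
#' @export
classification_metrics <- function(truth, predicted, labels) {
  K <- length(labels)
  stopifnot(length(truth) == length(predicted),
            all(truth >= 1L), all(truth <= K))
  conf <- matrix(0L, K, K, dimnames = list(truth = labels, predicted = labels))
  for (i in seq_along(truth))
    conf[truth[i], predicted[i]] <- conf[truth[i], predicted[i]] + 1L
  support <- rowSums(conf)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  N <- sum(conf)
  w <- support / N
  structure(list(
    confusion = conf,
    per_class = data.frame(label = labels, support = as.integer(support),
                           precision = prec, recall = rec, f1 = f1,
                           row.names = NULL),
    w_acc = sum(w * rec), w_f1 = sum(w * f1), n = N),
    class = "tf_metrics")
}

#' @export
print.tf_metrics <- function(x, ...) {
  cat(sprintf("n=%d  w-Acc=%.4f  w-F1=%.4f\n", x$n, x$w_acc, x$w_f1))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Write metrics as JSON plus a confusion-matrix CSV
#'
#' @param metrics a `tf_metrics`.
#' @param json_path output JSON path.
#' @param confusion_csv optional CSV path for the confusion matrix
#'   (rows = true labels in vocabulary order).
#' @export
write_metrics <- function(metrics, json_path, confusion_csv = NULL) {
  jsonlite::write_json(list(
    n = metrics$n, w_acc = metrics$w_acc, w_f1 = metrics$w_f1,
    per_class = metrics$per_class), json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_csv))
    utils::write.csv(as.data.frame(metrics$confusion), confusion_csv)
  invisible(json_path)
}
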