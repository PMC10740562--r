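#' Mean squared error
#'
#' `mean((x_hat - x)^2)` between a sequence and its reconstruction or
#' forecast; the metric used for both generative-model reconstruction error
#' and extrapolation error.
#'
#' @param x,x_hat equal-length numeric vectors.
#' @return a nonnegative scalar.
#' @examples
#' mse(c(0, 0), c(3, 4))  # 12.5
#' @export
mse <- function(x, x_hat) {
  if (length(x) != length(x_hat)) abort("`x` and `x_hat` must have equal length.")
  mean((x_hat - x)^2)
}

#' Confusion matrix and derived classification metrics
#'
#' Builds the m x m confusion matrix (rows = true class, columns =
#' predicted class) and derives overall accuracy (trace / total),
#' one-vs-rest precision (positive predictive value), recall (true
#' positive rate) and F1 per class, and the macro F1-score (unweighted mean
#' of class F1). When a class has `precision + recall = 0` (never predicted
#' and never correctly recovered) its F1 is defined as 0 and still enters
#' the macro mean.
#'
#' @param true_labels,predicted_labels integer vectors with values in
#'   `1..m`.
#' @param m number of classes.
#' @return an object of class `apta_metrics`: a list with `confusion`,
#'   `accuracy`, `per_class` (tibble of class, support, precision, recall,
#'   f1) and `macro_f1`. [tidy()] returns the per-class table, [glance()]
#'   a one-row summary.
#' @examples
#' rep <- confusion_and_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2), m = 2)
#' rep$accuracy
#' @export
confusion_and_metrics <- function(true_labels, predicted_labels, m) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("label vectors must have equal length.")
  }
  if (any(true_labels < 1 | true_labels > m) ||
      any(predicted_labels < 1 | predicted_labels > m)) {
    abort("labels must lie in 1..m.")
  }
  cm <- matrix(0L, m, m)
  for (i in seq_along(true_labels)) {
    cm[true_labels[i], predicted_labels[i]] <- cm[true_labels[i], predicted_labels[i]] + 1L
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  structure(list(
    confusion = cm,
    accuracy = sum(tp) / length(true_labels),
    per_class = tibble::tibble(class = seq_len(m), support = rowSums(cm),
                               precision = precision, recall = recall, f1 = f1),
    macro_f1 = mean(f1)
  ), class = "apta_metrics")
}

#' @export
print.apta_metrics <- function(x, ...) {
  cat(sprintf("<apta_metrics> %d classes | accuracy %.4f | macro-F1 %.4f\n",
              nrow(x$per_class), x$accuracy, x$macro_f1))
  invisible(x)
}

#' @rdname confusion_and_metrics
#' @param x an `apta_metrics` object.
#' @param ... unused.
#' @exportS3Method
tidy.apta_metrics <- function(x, ...) x$per_class

#' @rdname confusion_and_metrics
#' @exportS3Method
glance.apta_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 n = sum(x$confusion), n_classes = nrow(x$per_class))
}
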