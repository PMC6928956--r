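# Multiclass evaluation metrics. Balanced accuracy is the mean of per-class
# recalls over the classes present in the truth, which makes it robust to
# class imbalance; the macro false negative rate is its complement.

#' Balanced accuracy
#'
#' Mean over the classes present in `y_true` of the per-class recall. The
#' error rate reported by experiment traces is `1 - balanced_accuracy`.
#'
#' @param y_true true labels (non-empty).
#' @param y_pred predicted labels (same length).
#' @return A score in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("contract error: y_true and y_pred must be non-empty and equal length",
         call. = FALSE)
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Macro false negative rate
#'
#' Mean over the classes present in `y_true` of `1 - recall`; identically
#' `1 - balanced_accuracy(y_true, y_pred)`.
#'
#' @inheritParams balanced_accuracy
#' @return A score in `[0, 1]`.
#' @export
macro_fnr <- function(y_true, y_pred) {
  1 - balanced_accuracy(y_true, y_pred)
}
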