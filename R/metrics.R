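# Binary classification metrics. AUC-ROC is computed from tie-averaged
# ranks (the Mann-Whitney statistic); AUC-PR by step integration of the
# precision-recall curve.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties averaged: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param y_hat Numeric scores.
#' @param y 0/1 labels; both classes must be present.
#' @return Scalar in `[0, 1]`.
#' @export
auc_roc <- function(y_hat, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  r <- rank(y_hat)  # ties.method = "average"
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration (average precision): samples are sorted by decreasing
#' score and the precision at each recall increment is accumulated; tied
#' scores are processed as one block.
#'
#' @inheritParams auc_roc
#' @return Scalar in `(0, 1]`.
#' @export
auc_pr <- function(y_hat, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  if (n1 == 0L || n1 == length(y)) {
    stop("AUC-PR undefined: only one class present", call. = FALSE)
  }
  o <- order(y_hat, decreasing = TRUE)
  ys <- y[o]
  scores <- y_hat[o]
  # collapse tied scores into blocks
  blocks <- cumsum(!duplicated(scores))
  tp_block <- tapply(ys, blocks, sum)
  n_block <- tapply(ys, blocks, length)
  tp <- cumsum(tp_block)
  n <- cumsum(n_block)
  prec <- tp / n
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Threshold and ranking metrics for binary predictions
#'
#' Accuracy, recall, precision and F1 at the given probability threshold,
#' plus the threshold-free AUC-ROC and AUC-PR. With a single-class truth
#' vector the AUCs are undefined and returned as `NA` with `auc_defined =
#' FALSE`.
#'
#' @param y_hat Predicted probabilities.
#' @param y 0/1 labels.
#' @param threshold Classification threshold for the confusion-matrix
#'   metrics.
#' @return List of class `metric_report`.
#' @export
classification_metrics <- function(y_hat, y, threshold = 0.5) {
  if (length(y_hat) != length(y) || length(y) == 0L) {
    stop("`y_hat` and `y` must be non-empty and of equal length", call. = FALSE)
  }
  y <- as.integer(y)
  pred <- as.integer(y_hat >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  one_class <- length(unique(y)) < 2L
  structure(
    list(auc_roc = if (one_class) NA_real_ else auc_roc(y_hat, y),
         accuracy = (tp + tn) / length(y),
         recall = rec, precision = prec, f1 = f1,
         auc_pr = if (one_class) NA_real_ else auc_pr(y_hat, y),
         n = length(y), threshold = threshold, auc_defined = !one_class),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Binary classification metrics (n = ", x$n, ", threshold = ",
      x$threshold, ")\n", sep = "")
  for (m in c("auc_roc", "accuracy", "recall", "precision", "f1", "auc_pr")) {
    cat(sprintf("  %-9s %s\n", m,
                ifelse(is.na(x[[m]]), "undefined", sprintf("%.4f", x[[m]]))))
  }
  invisible(x)
}
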