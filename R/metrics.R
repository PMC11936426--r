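#' Confusion matrix from labels and predictions
#'
#' @param truth,pred integer class indices in `0..C-1` (or factors with the
#'   same levels).
#' @param n_classes number of classes `C`.
#' @return `C x C` integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  truth <- as_label_index(truth, n_classes)
  pred <- as_label_index(pred, n_classes)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = 0:(n_classes - 1L),
                               pred = 0:(n_classes - 1L)))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' One-vs-rest AUC by the rank statistic
#'
#' Area under the ROC curve computed via the Mann-Whitney U statistic with
#' midranks for ties: `AUC = (sum of positive ranks - n1(n1+1)/2) / (n1 n0)`.
#'
#' @param scores numeric scores, larger = more positive.
#' @param positive logical vector marking the positive class.
#' @return AUC in `[0, 1]`, or `NA` when either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full multi-class evaluation report
#'
#' Computes the confusion matrix from argmax predictions, per-class
#' precision/recall/F1 and one-vs-rest TP/TN/FP/FN counts, macro and micro
#' aggregates, and per-class one-vs-rest AUC from the predicted
#' probabilities (rank-statistic formulation). A class absent from the
#' labels gets `NA` AUC and is excluded from the macro AUC with a message.
#' Per-class precision or recall with an empty denominator is reported
#' as 0.
#'
#' @param truth integer class indices in `0..C-1` (or a factor).
#' @param probs `(N, C)` matrix of predicted class probabilities.
#' @param class_names optional character vector of length `C`.
#' @return an object of class `metrics_report`.
#' @export
metrics_report <- function(truth, probs, class_names = NULL) {
  probs <- as.matrix(probs)
  C <- ncol(probs); N <- nrow(probs)
  truth <- as_label_index(truth, C)
  if (is.null(class_names)) class_names <- as.character(0:(C - 1L))
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(truth, pred, C)

  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- N - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  auc <- vapply(seq_len(C), function(j)
    auc_rank(probs[, j], truth == j - 1L), 0)
  if (anyNA(auc))
    message("AUC undefined for class(es) ",
            paste(class_names[is.na(auc)], collapse = ", "),
            " (absent from labels); excluded from the macro average")

  per_class <- data.frame(class = class_names, support = rowSums(cm),
                          tp = tp, tn = tn, fp = fp, fn = fn,
                          precision = prec, recall = rec, f1 = f1, auc = auc)
  acc <- sum(tp) / N
  structure(list(
    confusion = cm,
    per_class = per_class,
    accuracy = acc,
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1), macro_auc = mean(auc, na.rm = TRUE),
    micro_precision = sum(tp) / sum(tp + fp),
    micro_recall = sum(tp) / sum(tp + fn),
    n = N
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Evaluation on", x$n, "samples\n")
  cat("  accuracy:", round(x$accuracy, digits),
      " macro F1:", round(x$macro_f1, digits),
      " macro AUC:", round(x$macro_auc, digits), "\n")
  cat("  macro precision/recall:", round(x$macro_precision, digits), "/",
      round(x$macro_recall, digits), "\n\nPer class:\n")
  pc <- x$per_class
  pc[sapply(pc, is.numeric)] <- lapply(pc[sapply(pc, is.numeric)], round,
                                       digits = digits)
  print(pc, row.names = FALSE)
  cat("\nConfusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

metrics_to_list <- function(x) {
  list(accuracy = x$accuracy,
       macro_precision = x$macro_precision, macro_recall = x$macro_recall,
       macro_f1 = x$macro_f1, macro_auc = x$macro_auc,
       micro_precision = x$micro_precision, micro_recall = x$micro_recall,
       n = x$n,
       per_class = x$per_class,
       confusion = unclass(x$confusion))
}
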