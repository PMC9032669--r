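# Confusion matrices, one-vs-rest accuracy/precision/recall/F1, and the
# stratified 70/20/10 split used to train and evaluate the classifiers.

#' Default class order
#' @export
WEED_CLASSES <- c("Crop", "NLW", "BLW")

#' Confusion matrix of true vs predicted labels
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted as
#' class `j`.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class order for rows/columns (default `Crop, NLW, BLW`).
#' @return an integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = WEED_CLASSES) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown) > 0)
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  cm <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  cm <- unclass(cm)
  dimnames(cm) <- list(true = classes, predicted = classes)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest counts and metrics from a confusion matrix
#'
#' For each class, the matrix is reduced one-vs-rest to TP/FP/FN/TN counts,
#' from which four metrics are derived: accuracy `(TP+TN)/(TP+TN+FP+FN)`,
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1, the harmonic mean of
#' precision and recall. A zero denominator yields a metric of 0 and sets the
#' `zero_division` flag for that class. Macro averages and the overall
#' accuracy (`trace/total` of the full matrix) are also reported.
#'
#' @param cm a `confusion_matrix`.
#' @param cls optional single class; when given only that class's entry is
#'   returned.
#' @return an object of class `metrics_report`: a list with `per_class` (data
#'   frame), `macro` (named numeric) and `overall_accuracy`.
#' @export
metrics_from_confusion <- function(cm, cls = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  safe_div <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  rows <- lapply(classes, function(k) {
    i <- match(k, classes)
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    acc <- safe_div(tp + tn, tp + tn + fp + fn)
    pre <- safe_div(tp, tp + fp)
    rec <- safe_div(tp, tp + fn)
    f1 <- if (pre[1] + rec[1] == 0) c(0, TRUE) else
      c(2 * pre[1] * rec[1] / (pre[1] + rec[1]), FALSE)
    data.frame(class = k, TP = tp, TN = tn, FP = fp, FN = fn,
               accuracy = acc[1], precision = pre[1], recall = rec[1],
               f1 = f1[1],
               zero_division = any(c(acc[2], pre[2], rec[2], f1[2]) == 1))
  })
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- NULL
  rep_ <- structure(list(
    per_class = per_class,
    macro = c(accuracy = mean(per_class$accuracy),
              precision = mean(per_class$precision),
              recall = mean(per_class$recall),
              f1 = mean(per_class$f1)),
    overall_accuracy = sum(diag(cm)) / total
  ), class = "metrics_report")
  if (!is.null(cls)) {
    if (!cls %in% classes) stop("unknown class: ", cls)
    return(per_class[per_class$class == cls, ])
  }
  rep_
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("overall accuracy:", sprintf("%.2f%%", 100 * x$overall_accuracy), "\n")
  df <- x$per_class
  df[, c("accuracy", "precision", "recall", "f1")] <-
    round(100 * df[, c("accuracy", "precision", "recall", "f1")], 2)
  print(df)
  cat("macro: ", paste(sprintf("%s %.2f%%", names(x$macro), 100 * x$macro),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate predictions end to end
#'
#' Convenience wrapper: builds the confusion matrix and the metrics report.
#'
#' @inheritParams confusion_matrix
#' @return a list with `confusion` and `metrics`.
#' @export
evaluate_predictions <- function(y_true, y_pred, classes = WEED_CLASSES) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  list(confusion = cm, metrics = metrics_from_confusion(cm))
}

#' Stratified train/validation/test split
#'
#' Splits item indices into disjoint, exhaustive subsets honouring the
#' requested fractions within every class. Subset sizes per class are
#' resolved by largest-remainder rounding; the assignment is reproducible
#' from `seed`.
#'
#' @param labels class label per item.
#' @param fractions length-3 fractions summing to 1 (default `0.7, 0.2, 0.1`
#'   for training, validation and testing).
#' @param seed RNG seed for shuffling within classes.
#' @return a list with integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(0.7, 0.2, 0.1), seed = 42) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative values summing to 1")
  labels <- as.character(labels)
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  rng <- local({ set.seed(seed); function(n) sample.int(n) })
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    idx <- idx[rng(length(idx))]
    counts <- largest_remainder(length(idx), fractions)
    cut1 <- counts[1]; cut2 <- counts[1] + counts[2]
    out$train <- c(out$train, idx[seq_len(cut1)])
    out$validation <- c(out$validation, idx[seq_len(cut2 - cut1) + cut1])
    out$test <- c(out$test, idx[seq_len(length(idx) - cut2) + cut2])
  }
  out
}

# Apportion n into parts proportional to fractions, largest remainder first
# (ties resolved in part order).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by <- order(exact - base, decreasing = TRUE)
    base[order_by[seq_len(rem)]] <- base[order_by[seq_len(rem)]] + 1
  }
  as.integer(base)
}
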