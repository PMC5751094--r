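# Confusion matrices, recall / precision / F-measure, CV drivers.

#' Confusion matrix of actual vs predicted labels
#'
#' Rows are actual classes, columns predicted classes; entry `(i, j)` counts
#' samples of actual class `i` predicted as class `j`.
#'
#' @param actual,predicted Label vectors of equal length.
#' @param classes Optional class roster (default: sorted union of labels).
#' @return A `confusion_matrix` (integer matrix with class dimnames).
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted))
    stop("actual and predicted have different lengths")
  actual <- as.character(actual); predicted <- as.character(predicted)
  classes <- classes %||% sort(unique(c(actual, predicted)))
  m <- table(factor(actual, classes), factor(predicted, classes))
  structure(matrix(as.integer(m), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `actual`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  cl <- rownames(x)
  tibble::tibble(actual = rep(cl, times = length(cl)),
                 predicted = rep(cl, each = length(cl)),
                 n = as.vector(unclass(x)))
}

#' Classification metrics from a confusion matrix
#'
#' Per class: recall `R = TP / actual-class count`, precision
#' `P = TP / predicted-class count` (0 when the class is never predicted),
#' error rate `1 - P`, and `F = 2 P R / (P + R)` (0 when `P + R = 0`). Macro
#' averages are unweighted class means; the micro recall equals overall
#' accuracy (trace over total).
#'
#' @param cm A [confusion_matrix()].
#' @return A `classification_metrics` object; see [tidy.classification_metrics()]
#'   and [glance.classification_metrics()].
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  tp <- diag(m)
  rs <- rowSums(m); cs <- colSums(m)
  recall <- ifelse(rs > 0, tp / rs, 0)
  precision <- ifelse(cs > 0, tp / cs, 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  by_class <- tibble::tibble(class = rownames(m), n = as.integer(rs),
                             recall = unname(recall),
                             precision = unname(precision),
                             error_rate = unname(1 - precision),
                             f_measure = unname(f))
  structure(list(by_class = by_class,
                 macro = list(recall = mean(recall),
                              precision = mean(precision),
                              error_rate = mean(1 - precision),
                              f_measure = mean(f)),
                 accuracy = sum(tp) / max(sum(m), 1),
                 confusion = cm),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("<classification_metrics> macro R %.4f | macro 1-P %.4f | macro F %.4f | accuracy %.4f\n",
              x$macro$recall, x$macro$error_rate, x$macro$f_measure, x$accuracy))
  invisible(x)
}

#' Per-class metrics as a tibble
#'
#' @param x A `classification_metrics` object.
#' @param ... Unused.
#' @return Tibble with one row per class.
#' @export
tidy.classification_metrics <- function(x, ...) x$by_class

#' One-row macro summary of classification metrics
#'
#' @param x A `classification_metrics` object.
#' @param ... Unused.
#' @return Tibble with macro recall/precision/error/F and overall accuracy.
#' @export
glance.classification_metrics <- function(x, ...) {
  tibble::tibble(macro_recall = x$macro$recall,
                 macro_precision = x$macro$precision,
                 macro_error_rate = x$macro$error_rate,
                 macro_f_measure = x$macro$f_measure,
                 accuracy = x$accuracy,
                 n = sum(x$by_class$n))
}

#' Stratified cross-validation of a generic train/predict pair
#'
#' Splits the samples into stratified folds (or one stratified holdout
#' half-split), fits on each training part and evaluates on the held-out
#' part. Everything fitted from data — feature selection, codebooks, shape
#' templates — must happen inside `train_fn`, which receives training indices
#' only.
#'
#' @param labels Class labels for all samples.
#' @param train_fn `function(train_idx)` returning a fitted object.
#' @param predict_fn `function(fit, test_idx)` returning predicted labels.
#' @param protocol `"kfold"` (every fold held out once) or `"holdout"` (one
#'   stratified half split: train on part 1, test on part 2).
#' @param k Number of folds (default 2).
#' @param seed Integer seed for the fold assignment.
#' @return A list with `per_fold` (list of `classification_metrics`),
#'   `pooled` (metrics of the pooled confusion matrix), `folds` (assignment
#'   vector).
#' @export
cross_validate <- function(labels, train_fn, predict_fn,
                           protocol = c("kfold", "holdout"), k = 2,
                           seed = 1) {
  protocol <- match.arg(protocol)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  fold <- make_folds(labels, k, seed)
  test_sets <- if (protocol == "holdout") list(which(fold == 2)) else
    lapply(seq_len(k), function(f) which(fold == f))
  per_fold <- list()
  actual_all <- character(0); pred_all <- character(0)
  for (i in seq_along(test_sets)) {
    test_idx <- test_sets[[i]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    fit <- train_fn(train_idx)
    pred <- as.character(predict_fn(fit, test_idx))
    per_fold[[i]] <- metrics(confusion_matrix(labels[test_idx], pred, classes))
    actual_all <- c(actual_all, labels[test_idx])
    pred_all <- c(pred_all, pred)
  }
  list(per_fold = per_fold,
       pooled = metrics(confusion_matrix(actual_all, pred_all, classes)),
       folds = fold)
}
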