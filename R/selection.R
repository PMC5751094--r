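# Per-group wrapper feature selection (sequential forward search scored by
# cross-validated accuracy of a linear SVM evaluator).

# Vectorized one-way ANOVA F score of every column of x against the labels.
anova_f_scores <- function(x, labels) {
  labels <- as.factor(labels)
  n <- nrow(x); g <- nlevels(labels)
  gm <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (lv in levels(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    ni <- nrow(xi)
    mi <- colMeans(xi)
    ssb <- ssb + ni * (mi - gm)^2
    ssw <- ssw + colSums((xi - matrix(mi, ni, ncol(x), byrow = TRUE))^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[!is.finite(f)] <- 0
  f
}

# Stratified fold assignment, deterministic given the seed. Errors naming
# any class smaller than k.
make_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small) > 0)
    stop(sprintf("class `%s` has fewer than %d samples", small[1], k))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# k-fold CV accuracy of a linear SVM (cost C) on the given feature columns.
cv_accuracy <- function(x, labels, fold, cols, C = 1) {
  labels <- factor(labels)
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, cols, drop = FALSE], labels[tr],
                      kernel = "linear", cost = C, scale = FALSE)
    pr <- stats::predict(fit, x[!tr, cols, drop = FALSE])
    correct <- correct + sum(pr == labels[!tr])
  }
  correct / length(labels)
}

#' Wrapper feature selection for one feature group
#'
#' Sequential forward selection scored by stratified k-fold cross-validated
#' accuracy of a linear SVM (cost `C = 1`): starting from the empty set, the
#' feature whose addition maximizes CV accuracy is added at each step (ties
#' to the lowest column index); the search keeps the best subset seen and
#' stops after `patience` consecutive non-improving additions or at the
#' retained-set cap. High-dimensional groups are first reduced to the top
#' `cap` columns by a one-way ANOVA F score, which bounds the quadratic
#' wrapper cost. Features are z-scored with training statistics before
#' evaluation. Deterministic given the seed.
#'
#' @param x Numeric matrix, samples by features (one group).
#' @param labels Class labels (at least 2 classes, each with at least
#'   `folds` samples).
#' @param folds CV folds for the evaluator (default 3).
#' @param seed Integer seed.
#' @param cap Candidate columns kept after F-score pre-ranking (default 64).
#' @param patience Consecutive non-improving steps tolerated (default 3).
#' @param max_features Cap on the retained set size (default 20).
#' @param C Evaluator SVM cost (default 1).
#' @return A `selection_result`: `indices` (ordered retained column indices
#'   into `x`), `trace` (tibble of step, feature, CV score), `score`.
#' @export
wrapper_select <- function(x, labels, folds = 3, seed = 1, cap = 64,
                           patience = 3, max_features = 20, C = 1) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("feature selection needs at least 2 classes")
  mu <- colMeans(x); sg <- apply(x, 2, stats::sd)
  sg[sg == 0] <- 1
  xs <- scale(x, center = mu, scale = sg)
  fold <- make_folds(labels, folds, seed)
  cand <- order(-anova_f_scores(xs, labels))[seq_len(min(cap, ncol(x)))]
  selected <- integer(0)
  best_set <- integer(0)
  best_score <- -Inf
  bad <- 0L
  rows <- list()
  step <- 0L
  while (length(cand) > 0 && length(selected) < max_features) {
    scores <- vapply(cand, function(j)
      cv_accuracy(xs, labels, fold, c(selected, j), C), 0)
    pick <- which.max(scores)          # ties: lowest candidate position
    step <- step + 1L
    selected <- c(selected, cand[pick])
    sc <- scores[pick]
    rows[[step]] <- tibble::tibble(step = step, feature = cand[pick],
                                   score = sc)
    cand <- cand[-pick]
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best_set <- selected
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  if (length(best_set) == 0) best_set <- selected[1]
  structure(list(indices = best_set, trace = dplyr::bind_rows(rows),
                 score = best_score),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features retained, CV score %.3f\n",
              length(x$indices), x$score))
  invisible(x)
}

#' Select features in every group of a feature group set
#'
#' Runs [wrapper_select()] independently on each group.
#'
#' @param groups Named list of sample-by-feature matrices sharing row order.
#' @param labels Class labels.
#' @param seed Integer seed (a distinct child seed is derived per group).
#' @param ... Passed to [wrapper_select()].
#' @return Named list of `selection_result` objects.
#' @export
select_features <- function(groups, labels, seed = 1, ...) {
  out <- lapply(seq_along(groups), function(i)
    wrapper_select(groups[[i]], labels, seed = child_seed(seed, i), ...))
  names(out) <- names(groups)
  out
}

#' Reduce a feature group set to its selected columns
#'
#' @param groups Named list of sample-by-feature matrices.
#' @param selection Named list of `selection_result` objects (or plain index
#'   vectors) covering the groups.
#' @return The groups, each reduced to its retained columns; sample order
#'   unchanged.
#' @export
apply_selection <- function(groups, selection) {
  out <- lapply(names(groups), function(g) {
    if (is.null(selection[[g]])) return(groups[[g]])
    idx <- if (inherits(selection[[g]], "selection_result"))
      selection[[g]]$indices else selection[[g]]
    if (any(idx < 1 | idx > ncol(groups[[g]])))
      stop(sprintf("selection indices out of bounds for group `%s`", g))
    groups[[g]][, idx, drop = FALSE]
  })
  names(out) <- names(groups)
  out
}
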