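# Confusion matrices, metrics, CV drivers.

test_that("confusion matrix counts actual-by-predicted pairs", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2,
                                   dimnames = list(actual = c("a", "b"),
                                                   predicted = c("a", "b"))))
  expect_error(confusion_matrix(c("a", "b"), "a"), "length")
  perfect <- confusion_matrix(rep(c("x", "y"), c(3, 5)),
                              rep(c("x", "y"), c(3, 5)))
  expect_equal(unname(diag(unclass(perfect))), c(3, 5))
  expect_equal(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0)
})

test_that("metrics reproduce the defining ratios", {
  cm <- structure(matrix(c(8L, 1L, 2L, 9L), 2,
                         dimnames = list(actual = c("a", "b"),
                                         predicted = c("a", "b"))),
                  class = "confusion_matrix")
  mt <- metrics(cm)
  td <- tidy(mt)
  expect_equal(td$recall, c(0.8, 0.9))
  expect_equal(td$precision, c(8 / 9, 9 / 11))
  expect_equal(td$error_rate, 1 - td$precision)
  # F equals P when P = R, and the harmonic mean otherwise
  expect_equal(2 * 0.9 * 0.8 / 1.7, 0.8470588, tolerance = 1e-6)
  f <- function(p, r) 2 * p * r / (p + r)
  expect_equal(td$f_measure, f(td$precision, td$recall))
  # trace/total equals accuracy
  expect_equal(mt$accuracy, (8 + 9) / 20)
})

test_that("perfect predictions give unit metrics for every class", {
  y <- rep(c("a", "b", "c"), times = c(4, 5, 6))
  mt <- metrics(confusion_matrix(y, y))
  td <- tidy(mt)
  expect_true(all(td$recall == 1 & td$precision == 1 & td$f_measure == 1))
  expect_equal(glance(mt)$macro_f_measure, 1)
})

test_that("F-measure is zero when precision and recall are both zero", {
  cm <- confusion_matrix(c("a", "a", "b"), c("b", "b", "a"))
  td <- tidy(metrics(cm))
  expect_equal(td$f_measure, c(0, 0))
})

test_that("cross-validation is stratified, deterministic and exhaustive", {
  labels <- rep(c("a", "b"), each = 10)
  seen <- list()
  cvres <- cross_validate(labels,
                          train_fn = function(tr) tr,
                          predict_fn = function(fit, te) {
                            seen[[length(seen) + 1]] <<- te
                            labels[te]
                          },
                          k = 2, seed = 5)
  fold <- cvres$folds
  expect_equal(unname(table(fold)), c(10L, 10L), ignore_attr = TRUE)
  for (f in 1:2)
    expect_equal(unname(table(labels[fold == f])), c(5L, 5L),
                 ignore_attr = TRUE)
  expect_identical(fold,
                   cross_validate(labels, function(tr) tr,
                                  function(fit, te) labels[te],
                                  k = 2, seed = 5)$folds)
  expect_equal(sum(tidy(cvres$pooled)$n), 20)   # pooled total = dataset size
  expect_error(cross_validate(c("a", rep("b", 9)), function(tr) tr,
                              function(fit, te) "b", k = 2, seed = 1),
               "class `a`")
})

test_that("a uniform random predictor scores near 1/C macro recall", {
  C <- 4; n_per <- 150
  labels <- rep(letters[1:C], each = n_per)
  preds <- withr::with_seed(31, sample(letters[1:C], C * n_per, replace = TRUE))
  mt <- metrics(confusion_matrix(labels, preds))
  sigma <- sqrt((1 / C) * (1 - 1 / C) / n_per)   # per-class binomial sd
  expect_lt(abs(mt$macro$recall - 1 / C), 3 * sigma / sqrt(C) + 3 * sigma)
})
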