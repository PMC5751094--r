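# Base kernels, nonlinear kernel combination, NLMKL training and prediction.

test_that("base kernels match entrywise brute-force formula evaluation", {
  X <- withr::with_seed(1, matrix(rnorm(15), 5, 3))
  Z <- withr::with_seed(2, matrix(rnorm(9), 3, 3))
  lin <- compute_kernel(X, Z, kernel_spec("linear"))
  pol <- compute_kernel(X, Z, kernel_spec("polynomial"))
  gau <- compute_kernel(X, Z, kernel_spec("gaussian", width = 1.3))
  for (i in 1:5) for (j in 1:3) {
    ip <- sum(X[i, ] * Z[j, ])
    expect_equal(lin[i, j], ip, tolerance = 1e-12)
    expect_equal(pol[i, j], (ip / 3 + 1)^3, tolerance = 1e-12)
    expect_equal(gau[i, j],
                 exp(-sum((X[i, ] - Z[j, ])^2) / (2 * 1.3^2)),
                 tolerance = 1e-12)
  }
  expect_error(compute_kernel(X, Z[, 1:2], kernel_spec("linear")), "differ")
})

test_that("gaussian self-kernel has a unit diagonal; linear on orthonormal rows is identity", {
  X <- withr::with_seed(3, matrix(rnorm(20), 4, 5))
  expect_equal(unname(diag(compute_kernel(X, spec = kernel_spec("gaussian")))),
               rep(1, 4))
  expect_equal(compute_kernel(diag(4), spec = kernel_spec("linear")), diag(4))
})

test_that("nlmkl_combine reproduces the multi-index expansion", {
  K1 <- diag(2); K2 <- matrix(1, 2, 2)
  expect_equal(nlmkl_combine(list(K1, K2), c(1, 1), 2),
               matrix(c(3, 1, 1, 3), 2))
  # p = 1: the d-th entrywise power; d = 1 is a pass-through
  K <- withr::with_seed(4, crossprod(matrix(rnorm(9), 3)))
  expect_equal(nlmkl_combine(list(K), 1, 1), K)
  expect_equal(nlmkl_combine(list(K), 1, 3), K^3)
  # general case against the enumeration oracle
  Ks <- lapply(1:3, function(i)
    withr::with_seed(i, crossprod(matrix(rnorm(16), 4))))
  eta <- c(0.5, 1.2, 0.3)
  for (d in 2:3)
    expect_equal(nlmkl_combine(Ks, eta, d), brute_nlmkl_combine(Ks, eta, d),
                 tolerance = 1e-10)
  expect_error(nlmkl_combine(Ks, c(-1, 1, 1), 2), "nonnegative")
})

test_that("combined kernels of PSD bases stay PSD", {
  for (s in 1:3) {
    Ks <- lapply(1:4, function(i)
      withr::with_seed(10 * s + i, crossprod(matrix(rnorm(60), 10, 6))))
    eta <- withr::with_seed(s, runif(4))
    Kc <- nlmkl_combine(Ks, eta, 2)
    expect_gte(min(eigen(Kc, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

svm_toy <- function(n = 40, seed = 3) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n, 1.5), n / 2, 2),
               matrix(rnorm(n, -1.5), n / 2, 2))
    list(X = X, y = rep(c("a", "b"), each = n / 2))
  })
}

test_that("degenerate single-kernel model matches the reference SVM dual", {
  toy <- svm_toy()
  m <- train_svm_single(toy$X, toy$y, "linear", C = 10)
  dec <- predict(m, toy$X, type = "decision")[, "a"]
  K <- toy$X %*% t(toy$X)
  K <- K * nrow(K) / sum(diag(K))
  ks <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(toy$y), C = 10,
                      type = "C-svc")
  co <- rep(0, 40); co[kernlab::SVindex(ks)] <- unlist(kernlab::coef(ks))
  fk <- as.vector(K %*% co - kernlab::b(ks))  # ksvm codes level "a" as -1
  expect_lt(max(abs(dec + fk)), 1e-4)
  J_ref <- -kernlab::obj(ks)
  expect_lt(abs(m$problems[["a"]]$objective - J_ref),
            1e-6 * max(1, abs(J_ref)))
})

test_that("four separable points are fit exactly at C = 100", {
  X <- rbind(c(1, 1), c(1, 2), c(-1, -1), c(-1, -2))
  y <- c("p", "p", "q", "q")
  m <- train_svm_single(X, y, "linear", C = 100)
  expect_identical(predict(m, X), y)
})

test_that("the informative group's kernel outweighs the noise group's", {
  toy <- make_gaussian_groups(n = 60, sep = 4, seed = 5)
  m <- train_nlmkl(toy$groups, toy$labels, families = "gaussian", C = 10)
  for (cl in m$classes) {
    eta <- m$problems[[cl]]$eta
    expect_gt(eta[1], eta[2])   # base 1 = group A (informative)
  }
})

test_that("the sequence of dual optima is monotone during training", {
  toy <- make_gaussian_groups(n = 40, sep = 2, seed = 9)
  m <- train_nlmkl(toy$groups, toy$labels,
                   families = c("gaussian", "linear"), C = 10)
  for (cl in m$classes) {
    tr <- m$problems[[cl]]$trace
    expect_true(all(diff(tr) <= 1e-6))
  }
})

test_that("predictions permute with the samples and match direct evaluation", {
  toy <- make_gaussian_groups(n = 40, sep = 4, seed = 2)
  m <- train_nlmkl(toy$groups, toy$labels, families = "linear", C = 10,
                   degree = 1)
  expect_identical(predict(m, toy$groups), toy$labels)  # separable training set
  test_groups <- lapply(toy$groups, function(g) g[c(5, 1, 20), ])
  p1 <- predict(m, test_groups)
  p2 <- predict(m, lapply(toy$groups, function(g) g[c(1, 5, 20), ]))
  expect_identical(p1, p2[c(2, 1, 3)])
  # decision values against a scalar re-implementation of the decision sum
  dec <- predict(m, test_groups, type = "decision")
  cl <- m$classes[1]
  pr <- m$problems[[cl]]
  y <- ifelse(m$labels == cl, 1, -1)
  for (i in 1:3) {
    f <- 0
    for (j in seq_along(y)) {
      kv <- 0
      for (b in seq_along(m$specs)) {
        sp <- m$specs[[b]]
        xi <- test_groups[[sp$group]][i, ]
        xj <- m$groups_train[[sp$group]][j, ]
        kraw <- sum(xi * xj) * m$factors[b]
        kv <- kv + pr$eta[b] * kraw   # degree 1, linear family
      }
      f <- f + pr$alpha[j] * y[j] * kv
    }
    expect_equal(unname(dec[i, cl]), f + pr$b, tolerance = 1e-8)
  }
})

test_that("training rejects degenerate inputs", {
  toy <- make_gaussian_groups(n = 20, seed = 1)
  bad <- toy$groups
  bad$A[1, 1] <- NA
  expect_error(train_nlmkl(bad, toy$labels), "finite")
  expect_error(train_nlmkl(toy$groups, rep("one", 20)), "2 classes")
})
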