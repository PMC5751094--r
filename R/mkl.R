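# Base kernels, nonlinear multiple kernel learning (polynomial combination
# of base kernels with learned nonnegative weights), one-vs-rest training
# and prediction, and the degenerate single-kernel SVM used for comparison.

#' Define a base kernel
#'
#' @param family One of `"linear"`, `"polynomial"`, `"gaussian"`.
#' @param width Gaussian width; when `NULL` it is set at training time by the
#'   median pairwise-distance heuristic on the group's training features.
#' @param degree Polynomial degree (default 3).
#' @param scale Polynomial inner-product scale; `NULL` means `1/d_features`.
#' @param group Source feature-group name (bookkeeping).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "gaussian"),
                        width = NULL, degree = 3, scale = NULL, group = NULL) {
  family <- match.arg(family)
  if (!is.null(width) && width <= 0) stop("gaussian width must be > 0")
  if (degree < 1) stop("polynomial degree must be >= 1")
  structure(list(family = family, width = width, degree = degree,
                 scale = scale, group = group),
            class = "kernel_spec")
}

#' Compute a base kernel matrix
#'
#' Linear: inner products. Polynomial: `(scale * <x, z> + 1)^degree`.
#' Gaussian: `exp(-||x - z||^2 / (2 width^2))`, with the width defaulting to
#' the median pairwise distance of `X`. Symmetric (and PSD) when `Z = X`.
#'
#' @param X,Z Sample-by-feature matrices with matching feature dimension
#'   (`Z` defaults to `X`).
#' @param spec A [kernel_spec()].
#' @return `nrow(X) x nrow(Z)` kernel matrix.
#' @export
compute_kernel <- function(X, Z = NULL, spec = kernel_spec("linear")) {
  X <- as.matrix(X)
  Z <- if (is.null(Z)) X else as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop("feature dimensions of X and Z differ")
  if (spec$family == "linear") {
    X %*% t(Z)
  } else if (spec$family == "polynomial") {
    s <- spec$scale %||% (1 / max(ncol(X), 1))
    (s * (X %*% t(Z)) + 1)^spec$degree
  } else {
    w <- spec$width %||% median_width(X)
    d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * X %*% t(Z)
    exp(-pmax(d2, 0) / (2 * w^2))
  }
}

# Median pairwise-distance heuristic for the Gaussian width.
median_width <- function(X) {
  n <- nrow(X)
  if (n > 200) X <- X[seq_len(200), , drop = FALSE]
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

# Scale a training kernel so its trace equals n; returns the matrix and the
# factor (to be reused on cross kernels at prediction time).
trace_normalize <- function(K) {
  f <- nrow(K) / sum(diag(K))
  if (!is.finite(f) || f <= 0) f <- 1
  list(K = K * f, factor = f)
}

# All multi-indices (k_1, ..., k_p) with sum k = d, as rows.
multi_indices <- function(p, d) {
  if (p == 1) return(matrix(d, 1, 1))
  out <- list()
  for (k1 in d:0) {
    rest <- multi_indices(p - 1, d - k1)
    out[[length(out) + 1]] <- cbind(k1, rest)
  }
  unname(do.call(rbind, out))
}

#' Nonlinear (polynomial) combination of base kernels
#'
#' \deqn{K_\eta = \sum_{k_1 + \cdots + k_p = d}
#'   \eta_1^{k_1} \cdots \eta_p^{k_p} \; K_1^{k_1} \circ \cdots \circ
#'   K_p^{k_p}}
#' where powers and products of kernel matrices are taken entrywise. Since
#' entrywise products of PSD matrices are PSD and the weights are
#' nonnegative, the combination is PSD.
#'
#' @param bases List of kernel matrices of equal shape.
#' @param eta Nonnegative weights, one per base.
#' @param degree Combination degree `d >= 1`.
#' @return Combined kernel matrix.
#' @export
nlmkl_combine <- function(bases, eta, degree = 2) {
  p <- length(bases)
  stopifnot(length(eta) == p, degree >= 1)
  if (any(eta < 0)) stop("combination weights must be nonnegative")
  if (degree == 2) {
    # closed form: (U o U + sum eta_m^2 K_m o K_m) / 2, U = sum eta_m K_m
    U <- 0
    S <- 0
    for (m in seq_len(p)) {
      U <- U + eta[m] * bases[[m]]
      S <- S + eta[m]^2 * bases[[m]]^2
    }
    return((U^2 + S) / 2)
  }
  mi <- multi_indices(p, degree)
  out <- 0
  for (r in seq_len(nrow(mi))) {
    k <- mi[r, ]
    w <- prod(eta^k)
    if (w == 0) next
    term <- 1
    for (m in which(k > 0)) term <- term * bases[[m]]^k[m]
    out <- out + w * term
  }
  out
}

# Soft-margin SVM dual on a precomputed kernel, solved as a QP (interior
# point). Returns the full alpha vector, the bias (from free support
# vectors, with a KKT-interval fallback), the dual objective, and the
# training decision values.
solve_svm_dual <- function(K, y, C, ridge = 1e-8) {
  n <- length(y)
  H <- (y %*% t(y)) * K + diag(ridge, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0)
  alpha <- pmin(pmax(kernlab::primal(sol), 0), C)
  a <- alpha * y
  f0 <- as.vector(K %*% a)
  # bias: minimize the (convex, piecewise-linear in b) primal objective at
  # this alpha — at the exact optimum this coincides with the KKT bias of
  # the free support vectors, and it stays well-defined without them
  primal_b <- function(b)
    0.5 * sum(a * f0) + C * sum(pmax(0, 1 - y * (f0 + b)))
  rng <- range(y - f0)
  b <- stats::optimize(primal_b, c(rng[1] - 1, rng[2] + 1), tol = 1e-10)$minimum
  J <- sum(alpha) - 0.5 * sum(a * f0)
  list(alpha = alpha, b = b, objective = J, decision = f0 + b)
}

# Projection onto {eta >= 0, ||eta||_2 <= Lambda}.
project_eta <- function(eta, Lambda) {
  eta <- pmax(eta, 0)
  nrm <- sqrt(sum(eta^2))
  if (nrm > Lambda) eta <- eta * Lambda / nrm
  eta
}

# Danskin gradient of the dual optimum w.r.t. eta at the current alpha:
# dJ/deta_m = -1/2 a' (dK/deta_m) a, with a = alpha * y. For degree 2,
# dK/deta_m = K_m o (U + eta_m K_m) with U = sum eta K.
eta_gradient <- function(bases, eta, degree, a) {
  p <- length(bases)
  if (degree == 2) {
    U <- 0
    for (m in seq_len(p)) U <- U + eta[m] * bases[[m]]
    return(vapply(seq_len(p), function(m) {
      dK <- bases[[m]] * (U + eta[m] * bases[[m]])
      -0.5 * drop(t(a) %*% dK %*% a)
    }, 0))
  }
  mi <- multi_indices(p, degree)
  s <- vapply(seq_len(nrow(mi)), function(r) {
    k <- mi[r, ]
    term <- 1
    for (m in which(k > 0)) term <- term * bases[[m]]^k[m]
    drop(t(a) %*% term %*% a)
  }, 0)
  vapply(seq_len(p), function(m) {
    g <- 0
    for (r in seq_len(nrow(mi))) {
      k <- mi[r, ]
      if (k[m] < 1) next
      km <- k; km[m] <- km[m] - 1
      g <- g + k[m] * prod(eta^km) * s[r]
    }
    -0.5 * g
  }, 0)
}

# One binary NLMKL problem: alternate (a) exact dual solve at fixed eta and
# (b) a projected gradient step on eta descending the dual optimum (the
# kernel-learning direction: a better-aligned kernel attains a larger
# margin, i.e. a smaller dual optimum). A step is accepted only if the
# re-solved dual optimum does not increase, so the sequence of dual optima
# is nonincreasing.
train_binary_nlmkl <- function(bases, y, C, degree, Lambda, max_iter, tol,
                               optimize_eta = TRUE) {
  p <- length(bases)
  eta <- rep(Lambda / sqrt(p), p)
  if (!optimize_eta) eta <- rep(1, p)
  K <- nlmkl_combine(bases, eta, degree)
  sol <- solve_svm_dual(K, y, C)
  trace <- sol$objective
  converged <- FALSE
  step <- 1
  if (optimize_eta && p > 1) {
    for (it in seq_len(max_iter)) {
      a <- sol$alpha * y
      g <- eta_gradient(bases, eta, degree, a)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) { converged <- TRUE; break }
      accepted <- FALSE
      for (try in 1:6) {
        eta_new <- project_eta(eta - step * Lambda * g / gn, Lambda)
        if (max(abs(eta_new - eta)) < 1e-12) break
        K_new <- nlmkl_combine(bases, eta_new, degree)
        sol_new <- solve_svm_dual(K_new, y, C)
        if (sol_new$objective <= sol$objective + 1e-9) {
          eta <- eta_new
          delta <- sol$objective - sol_new$objective
          sol <- sol_new
          trace <- c(trace, sol$objective)
          accepted <- TRUE
          if (delta < tol) converged <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted || converged) { converged <- converged || !accepted; break }
    }
  } else converged <- TRUE
  list(alpha = sol$alpha, b = sol$b, eta = eta, objective = sol$objective,
       trace = trace, converged = converged)
}

#' Train a nonlinear multiple kernel learning classifier
#'
#' Builds one base kernel per (feature group, kernel family) pair — each
#' trace-normalized so no group's scale dominates — and learns, per
#' one-vs-rest binary problem, the combination weights \eqn{\eta} of the
#' degree-`degree` polynomial kernel combination together with the SVM dual
#' coefficients, by alternating an exact dual solve with projected gradient
#' steps on \eqn{\eta} over \eqn{\{\eta \ge 0, \|\eta\|_2 \le \Lambda\}}.
#' Deterministic given the inputs.
#'
#' @param groups Named list of sample-by-feature matrices (shared row order).
#' @param labels Class labels (>= 2 classes).
#' @param families Kernel families to use, subset of
#'   `c("gaussian", "polynomial", "linear")`.
#' @param C Soft-margin cost (the comparison experiments use the grid
#'   1, 10, 100).
#' @param degree Combination degree (default 2).
#' @param Lambda Bound on `||eta||_2` (default 1).
#' @param max_iter Maximum alternating iterations (default 50).
#' @param tol Stop when the dual optimum changes by less than this
#'   (default 1e-4).
#' @param seed Integer seed (recorded; training itself is deterministic).
#' @param optimize_eta Set `FALSE` to keep `eta` fixed at 1 (used by the
#'   degenerate single-kernel configuration).
#' @return An `mkl_model`.
#' @export
train_nlmkl <- function(groups, labels,
                        families = c("gaussian", "polynomial", "linear"),
                        C = 10, degree = 2, Lambda = 1, max_iter = 50,
                        tol = 1e-4, seed = 1, optimize_eta = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 1)
  families <- match.arg(families, c("gaussian", "polynomial", "linear"),
                        several.ok = TRUE)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training needs at least 2 classes")
  groups <- lapply(groups, as.matrix)
  if (!all(vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stop("non-finite feature values")
  n <- nrow(groups[[1]])
  specs <- list(); bases <- list(); factors <- numeric(0)
  i <- 0L
  for (g in names(groups)) {
    for (fam in families) {
      i <- i + 1L
      sp <- kernel_spec(fam, group = g)
      if (fam == "gaussian") sp$width <- median_width(groups[[g]])
      if (fam == "polynomial") sp$scale <- 1 / max(ncol(groups[[g]]), 1)
      K <- compute_kernel(groups[[g]], spec = sp)
      tn <- trace_normalize(K)
      specs[[i]] <- sp
      bases[[i]] <- tn$K
      factors[i] <- tn$factor
    }
  }
  problems <- lapply(classes, function(cl) {
    y <- ifelse(labels == cl, 1, -1)
    train_binary_nlmkl(bases, y, C, degree, Lambda, max_iter, tol,
                       optimize_eta)
  })
  names(problems) <- classes
  warned <- !vapply(problems, `[[`, TRUE, "converged")
  if (any(warned))
    warning(sprintf("eta optimization hit max_iter for: %s",
                    paste(classes[warned], collapse = ", ")))
  structure(list(classes = classes, problems = problems, specs = specs,
                 factors = factors, groups_train = groups, labels = labels,
                 families = families, C = C, degree = degree,
                 Lambda = Lambda, seed = seed,
                 converged = !any(warned)),
            class = "mkl_model")
}

#' Train a single-kernel SVM on concatenated features
#'
#' The degenerate multiple-kernel configuration: one feature block, one
#' kernel family, combination weight fixed at 1 and degree 1, so the decision
#' function is a plain soft-margin SVM. Used as the baseline in the
#' system-comparison experiments.
#'
#' @param features Sample-by-feature matrix (concatenated groups).
#' @param labels Class labels.
#' @param family Kernel family.
#' @param C Soft-margin cost (grid 1, 10, 100 in the comparisons).
#' @param seed Integer seed (recorded).
#' @return An `mkl_model` with a single base kernel per problem.
#' @export
train_svm_single <- function(features, labels, family = "gaussian", C = 10,
                             seed = 1) {
  train_nlmkl(list(all = as.matrix(features)), labels, families = family,
              C = C, degree = 1, seed = seed, optimize_eta = FALSE)
}

#' Predict classes with a trained MKL model
#'
#' Computes, per one-vs-rest problem, the decision value
#' \eqn{f(x) = \sum_i \alpha_i y_i K_\eta(x_i, x) + b} through cross kernels
#' against the stored training snapshot (reusing the training trace factors
#' and kernel parameters), and returns the class with the largest decision
#' value; ties break to the lowest class index.
#'
#' @param object An `mkl_model`.
#' @param groups Named list of feature matrices with the same group roster
#'   and columns as at training (for [train_svm_single()] models, either the
#'   concatenated matrix or `list(all = ...)`).
#' @param type `"class"` (default) or `"decision"` (matrix of decision
#'   values, samples by classes).
#' @param ... Unused.
#' @return Character vector of predicted labels, or the decision matrix.
#' @method predict mkl_model
#' @export
predict.mkl_model <- function(object, groups, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  if (is.matrix(groups) || is.data.frame(groups))
    groups <- list(all = as.matrix(groups))
  groups <- lapply(groups, as.matrix)
  if (!identical(sort(names(groups)), sort(names(object$groups_train))))
    stop("group roster does not match the trained model")
  crosses <- lapply(seq_along(object$specs), function(i) {
    sp <- object$specs[[i]]
    Xt <- object$groups_train[[sp$group]]
    Xn <- groups[[sp$group]]
    if (ncol(Xn) != ncol(Xt))
      stop(sprintf("group `%s` dimension mismatch", sp$group))
    compute_kernel(Xn, Xt, sp) * object$factors[i]
  })
  dec <- vapply(object$classes, function(cl) {
    pr <- object$problems[[cl]]
    Kc <- nlmkl_combine(crosses, pr$eta, object$degree)
    as.vector(Kc %*% (pr$alpha * ifelse(object$labels == cl, 1, -1)) + pr$b)
  }, numeric(nrow(groups[[1]])))
  dec <- matrix(dec, ncol = length(object$classes),
                dimnames = list(NULL, object$classes))
  if (type == "decision") return(dec)
  object$classes[apply(dec, 1, which.max)]
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("<mkl_model> %d classes, %d base kernels (%s), C=%g, degree=%d\n",
              length(x$classes), length(x$specs),
              paste(x$families, collapse = "+"), x$C, x$degree))
  invisible(x)
}

#' Tidy a fitted MKL model
#'
#' One row per (one-vs-rest problem, base kernel) with the learned
#' combination weight.
#'
#' @param x An `mkl_model`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `group`, `family`, `eta`.
#' @export
tidy.mkl_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$classes, function(cl) {
    tibble::tibble(
      class = cl,
      group = vapply(x$specs, function(s) s$group %||% "all", ""),
      family = vapply(x$specs, `[[`, "", "family"),
      eta = x$problems[[cl]]$eta)
  }))
}

#' One-row summary of a fitted MKL model
#'
#' @param x An `mkl_model`.
#' @param ... Unused.
#' @return A tibble with the model's size, settings, mean dual optimum and
#'   convergence flag.
#' @export
glance.mkl_model <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$groups_train[[1]]),
    n_classes = length(x$classes),
    n_kernels = length(x$specs),
    C = x$C, degree = x$degree, Lambda = x$Lambda,
    mean_objective = mean(vapply(x$problems, `[[`, 0, "objective")),
    n_support = mean(vapply(x$problems, function(p) sum(p$alpha > 1e-6), 0)),
    converged = x$converged)
}
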