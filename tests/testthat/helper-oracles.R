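# Independent oracles, written without reference to the package internals.

# 8-connected component areas by plain R flood fill.
flood_fill_areas <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  areas <- integer(0)
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; a <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      a <- a + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
    areas <- c(areas, a)
  }
  areas
}

# Discrete disk kernel offsets of diameter d.
disk_offsets <- function(d) {
  r <- d / 2
  half <- floor(r)
  g <- expand.grid(i = -half:half, j = -half:half)
  g[g$i^2 + g$j^2 <= r^2, , drop = FALSE]
}

# Brute-force opening: erosion by translate-and-fit (off-image counts as
# background), then dilation of the eroded set.
brute_opening <- function(mask, d) {
  off <- disk_offsets(d)
  h <- nrow(mask); w <- ncol(mask)
  er <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    rr <- r + off$i; cc <- c + off$j
    if (all(rr >= 1 & rr <= h & cc >= 1 & cc <= w) &&
        all(mask[cbind(rr, cc)])) er[r, c] <- TRUE
  }
  dl <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!er[r, c]) next
    rr <- r + off$i; cc <- c + off$j
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    dl[cbind(rr[ok], cc[ok])] <- TRUE
  }
  dl
}

# Direct double-loop "same" linear convolution with a complex kernel
# (zero padding outside the image).
brute_conv_complex <- function(I, ker) {
  half <- (nrow(ker) - 1) / 2
  h <- nrow(I); w <- ncol(I)
  out <- matrix(0 + 0i, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 0 + 0i
    for (dr in -half:half) for (dc in -half:half) {
      rr <- r - dr; cc <- c - dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w)
        acc <- acc + I[rr, cc] * ker[dr + half + 1, dc + half + 1]
    }
    out[r, c] <- acc
  }
  out
}

# Brute-force variogram at one lag, averaged over the given offsets.
brute_variogram <- function(I, offsets) {
  mean(vapply(offsets, function(d) {
    s <- 0; n <- 0
    for (r in seq_len(nrow(I))) for (c in seq_len(ncol(I))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nrow(I) && c2 >= 1 && c2 <= ncol(I)) {
        s <- s + (I[r, c] - I[r2, c2])^2
        n <- n + 1
      }
    }
    s / (2 * n)
  }, 0))
}

# LBP code of the pixel at (r, c) by explicit neighbor enumeration.
brute_lbp_code <- function(img, r, c) {
  nb <- c(img[r - 1, c - 1], img[r - 1, c], img[r - 1, c + 1], img[r, c + 1],
          img[r + 1, c + 1], img[r + 1, c], img[r + 1, c - 1], img[r, c - 1])
  sum((nb >= img[r, c]) * 2^(7:0))
}

# BGC1 code by listing the 8 cyclic sign bits then applying the weighted sum
# minus one (ties binarize to 1).
brute_bgc1_code <- function(patch) {
  I <- c(patch[1, 1], patch[1, 2], patch[1, 3], patch[2, 3],
         patch[3, 3], patch[3, 2], patch[3, 1], patch[2, 1])  # I0..I7
  s <- function(x) as.numeric(x >= 0)
  g <- c(s(I[8] - I[1]), s(I[7] - I[8]), s(I[6] - I[7]), s(I[5] - I[6]),
         s(I[4] - I[5]), s(I[3] - I[4]), s(I[2] - I[3]), s(I[1] - I[2]))
  sum(g * 2^(7:0)) - 1
}

# Chi-squared/2 cost by direct summation.
brute_chi2 <- function(a, b) {
  acc <- 0
  for (k in seq_along(a)) {
    s <- a[k] + b[k]
    if (s > 0) acc <- acc + (a[k] - b[k])^2 / s
  }
  acc / 2
}

# Exhaustive minimum-cost order-preserving circular matching with skips:
# plain recursion over match / skip-row / skip-col choices, over all start
# offsets. Exponential; for n <= 6 only.
brute_match <- function(C, pen) {
  n <- nrow(C); m <- ncol(C)
  best <- Inf
  for (s in 0:(m - 1)) {
    rec <- function(i, j) {
      if (i > n && j > m) return(0)
      v <- Inf
      if (i <= n && j <= m)
        v <- min(v, C[i, (j - 1 + s) %% m + 1] + rec(i + 1, j + 1))
      if (i <= n) v <- min(v, pen + rec(i + 1, j))
      if (j <= m) v <- min(v, pen + rec(i, j + 1))
      v
    }
    best <- min(best, rec(1, 1))
  }
  best
}

# Multi-index polynomial kernel combination by explicit enumeration
# (recursive composition listing, entrywise matrix products).
brute_nlmkl_combine <- function(bases, eta, d) {
  p <- length(bases)
  out <- 0
  comp <- function(prefix, left, slots) {
    if (slots == 1) return(list(c(prefix, left)))
    res <- list()
    for (k in left:0) res <- c(res, comp(c(prefix, k), left - k, slots - 1))
    res
  }
  for (k in comp(integer(0), d, p)) {
    term <- matrix(1, nrow(bases[[1]]), ncol(bases[[1]]))
    for (m in seq_len(p)) if (k[m] > 0) term <- term * bases[[m]]^k[m]
    out <- out + prod(eta^k) * term
  }
  out
}

# Random blobby test mask: union of a few disks, away from the border.
random_blob_mask <- function(h, w, n_disks = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, h, w)
    ri <- matrix(seq_len(h), h, w); ci <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n_disks)) {
      r0 <- runif(1, h * 0.3, h * 0.7); c0 <- runif(1, w * 0.3, w * 0.7)
      rad <- runif(1, min(h, w) * 0.1, min(h, w) * 0.22)
      m <- m | ((ri - r0)^2 + (ci - c0)^2 <= rad^2)
    }
    m
  })
}

# Two-group Gaussian toy data: group A separates the classes (separation
# `sep` in units of the within-class sd), group B is pure noise.
make_gaussian_groups <- function(n = 80, d = 3, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    half <- n %/% 2
    shift <- sep / 2
    A <- rbind(matrix(rnorm(half * d, +shift), half, d),
               matrix(rnorm((n - half) * d, -shift), n - half, d))
    B <- matrix(rnorm(n * d), n, d)
    list(groups = list(A = A, B = B),
         labels = rep(c("pos", "neg"), c(half, n - half)))
  })
}
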