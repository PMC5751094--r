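# Texture descriptors: Gabor filter bank, variogram, grid LBP, BGC1.

#' Construct a Gabor filter bank
#'
#' Complex Gabor filters
#' \deqn{g(x,y) = \frac{1}{2\pi\sigma^2}
#'   e^{-\frac{x^2+y^2}{2\sigma^2} + 2\pi j F (x\cos\theta + y\sin\theta)}}
#' over a grid of center frequencies and orientations. Defaults follow the
#' standard octave construction: \eqn{F_k = F_{max}/\sqrt{2}^k} for
#' \eqn{k = 0..5} cycles/pixel, \eqn{\theta_j = j\pi/8} for \eqn{j = 0..7},
#' and a constant-bandwidth envelope \eqn{\sigma = 0.56/F}, giving the 6 x 8
#' = 48-filter bank.
#'
#' @param n_freq Number of center frequencies (default 6).
#' @param n_orient Number of orientations (default 8).
#' @param f_max Highest center frequency in cycles/pixel (default 0.25).
#' @return A `gabor_bank` object (list of complex filter rasters with their
#'   parameters, plus an FFT cache).
#' @export
gabor_bank <- function(n_freq = 6, n_orient = 8, f_max = 0.25) {
  filters <- list()
  i <- 0L
  for (k in seq_len(n_freq) - 1L) {
    f <- f_max / sqrt(2)^k
    sigma <- 0.56 / f
    half <- ceiling(3 * sigma)
    xs <- -half:half
    X <- matrix(xs, length(xs), length(xs))
    Y <- t(X)
    env <- exp(-(X^2 + Y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
    for (j in seq_len(n_orient) - 1L) {
      th <- j * pi / n_orient
      phase <- 2 * pi * f * (X * cos(th) + Y * sin(th))
      i <- i + 1L
      filters[[i]] <- list(freq = f, theta = th, sigma = sigma, half = half,
                           kernel = env * exp(1i * phase))
    }
  }
  structure(list(filters = filters, n_freq = n_freq, n_orient = n_orient,
                 cache = new.env(parent = emptyenv())),
            class = "gabor_bank")
}

# "Same"-size linear convolution of a real image with every complex filter of
# the bank, by FFT with zero padding. Filter FFTs are cached per padded size.
gabor_responses <- function(image, bank) {
  h <- nrow(image); w <- ncol(image)
  maxk <- 2 * max(vapply(bank$filters, `[[`, 0, "half")) + 1
  P1 <- stats::nextn(h + maxk - 1, 2)
  P2 <- stats::nextn(w + maxk - 1, 2)
  key <- paste(P1, P2, sep = "x")
  if (is.null(bank$cache[[key]])) {
    bank$cache[[key]] <- lapply(bank$filters, function(f) {
      kp <- matrix(0 + 0i, P1, P2)
      d <- 2 * f$half + 1
      kp[seq_len(d), seq_len(d)] <- f$kernel
      stats::fft(kp)
    })
  }
  kffts <- bank$cache[[key]]
  ip <- matrix(0, P1, P2)
  ip[seq_len(h), seq_len(w)] <- image
  fi <- stats::fft(ip)
  lapply(seq_along(bank$filters), function(i) {
    half <- bank$filters[[i]]$half
    full <- stats::fft(fi * kffts[[i]], inverse = TRUE) / (P1 * P2)
    Mod(full[half + seq_len(h), half + seq_len(w)])
  })
}

#' Gabor texture features
#'
#' Convolves the image with every filter of the bank
#' (\eqn{Q = I * g}) and summarizes each response magnitude by its mean and
#' (population) standard deviation over the image support, yielding
#' `2 * n_freq * n_orient` values (96 for the default bank). Ordering is
#' frequency-major, orientation-minor, mean before std within each filter.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param bank A [gabor_bank()].
#' @return Named numeric vector (attribute `group` = `"gabor"`).
#' @export
gabor_features <- function(image, bank = gabor_bank()) {
  assert_gray_image(image)
  resp <- gabor_responses(image, bank)
  mn <- prod(dim(image))
  vals <- unlist(lapply(resp, function(M) {
    m <- sum(M) / mn
    c(m, sqrt(sum((M - m)^2) / mn))
  }))
  nms <- unlist(lapply(seq_along(bank$filters), function(i) {
    f <- bank$filters[[i]]
    base <- sprintf("f%.4f_t%d", f$freq, round(f$theta / pi * bank$n_orient))
    paste0(base, c("_mean", "_std"))
  }))
  feature_vector(vals, nms, "gabor")
}

#' Variogram texture features
#'
#' The empirical variogram
#' \deqn{\gamma(h) = \frac{1}{2N(h)} \sum_{i=1}^{N(h)} [I(x_i) - I(x_i+h)]^2}
#' evaluated at a set of pixel lags, averaging the four directions 0, 45, 90
#' and 135 degrees. When a mask is supplied the variogram is computed over
#' the mask's bounding box, focusing the statistic on the organism.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param mask Optional logical mask restricting computation to its bounding
#'   box.
#' @param lags Integer pixel lags; the default log-spaced roster
#'   `c(1, 2, 3, 4, 6, 8, 12, 16)` covers fine-to-coarse texture.
#' @param directions Angles (degrees) of the averaged lag directions, any
#'   subset of `c(0, 45, 90, 135)`; 0 is the horizontal (across-column)
#'   direction.
#' @return Named numeric vector of \eqn{\gamma} values, one per lag
#'   (attribute `group` = `"variogram"`).
#' @export
variogram_features <- function(image, mask = NULL,
                               lags = c(1, 2, 3, 4, 6, 8, 12, 16),
                               directions = c(0, 45, 90, 135)) {
  assert_gray_image(image)
  sub <- image
  if (!is.null(mask) && any(mask)) {
    assert_mask(mask, image)
    pts <- which(mask, arr.ind = TRUE)
    sub <- image[min(pts[, 1]):max(pts[, 1]), min(pts[, 2]):max(pts[, 2]),
                 drop = FALSE]
  }
  h <- nrow(sub); w <- ncol(sub)
  vals <- vapply(lags, function(l) {
    if (l >= min(h, w))
      stop(sprintf("lag %d exceeds the image extent %dx%d", l, h, w))
    all_dirs <- list(`0` = c(0, l), `90` = c(l, 0), `45` = c(l, l),
                     `135` = c(l, -l))
    dirs <- all_dirs[as.character(directions)]
    mean(vapply(dirs, function(d) {
      r1 <- seq_len(h - d[1])
      c1 <- if (d[2] >= 0) seq_len(w - d[2]) else (1 - d[2]):w
      dif <- sub[r1, c1, drop = FALSE] -
        sub[r1 + d[1], c1 + d[2], drop = FALSE]
      mean(dif^2) / 2
    }, 0))
  }, 0)
  feature_vector(vals, paste0("gamma_", lags), "variogram")
}

# 8-neighbor binary code of every interior pixel: neighbors clockwise from
# the top-left, bit set when neighbor >= center, most significant bit first.
lbp_codes <- function(image) {
  h <- nrow(image); w <- ncol(image)
  ctr <- image[2:(h - 1), 2:(w - 1), drop = FALSE]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- array(0, dim(ctr))
  for (k in seq_along(offs)) {
    d <- offs[[k]]
    nb <- image[2:(h - 1) + d[1], 2:(w - 1) + d[2], drop = FALSE]
    code <- code + (nb >= ctr) * 2^(8 - k)
  }
  code
}

#' Grid local binary pattern features
#'
#' Labels every interior pixel with its 8-bit LBP code (neighbor at least as
#' bright as the center contributes a 1-bit; neighbors read clockwise from
#' the top-left), partitions the code field into a `grid x grid` array of
#' cells, and concatenates the per-cell 256-bin code histograms row-major.
#' The cell decomposition preserves part-based locality of the texture.
#'
#' @param image Numeric matrix, at least `3 x 3` per cell.
#' @param grid Cells per side (default 4, giving a 4096-dimensional vector).
#' @return Named numeric vector of concatenated histograms (attribute
#'   `group` = `"lbp"`).
#' @export
lbp_features <- function(image, grid = 4) {
  assert_gray_image(image)
  code <- lbp_codes(image)
  h <- nrow(code); w <- ncol(code)
  stopifnot(h >= grid, w >= grid)
  rb <- floor(seq(0, h, length.out = grid + 1))
  cb <- floor(seq(0, w, length.out = grid + 1))
  out <- numeric(0); nms <- character(0)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      cell <- code[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], drop = FALSE]
      out <- c(out, tabulate(as.vector(cell) + 1L, nbins = 256L))
      nms <- c(nms, sprintf("c%d_%d_b%d", i, j, 0:255))
    }
  }
  feature_vector(out, nms, "lbp")
}

#' Single-loop binary gradient contour features
#'
#' For every interior pixel, the eight cyclic pairwise gradients along the
#' closed path of its 3 x 3 neighborhood are binarized
#' (\eqn{s(x) = 1} for \eqn{x > 0}, \eqn{0} for \eqn{x < 0}; ties count as 1
#' so the code range is closed) and read as an 8-bit word minus one, giving
#' codes in `[0, 254]` (the all-zeros loop is impossible). The descriptor is
#' the 255-bin histogram of these codes, normalized to sum to one.
#'
#' @param image Numeric matrix, at least `3 x 3`.
#' @return Named numeric vector of length 255 (attribute `group` = `"bgc"`).
#' @export
bgc1_features <- function(image) {
  assert_gray_image(image)
  h <- nrow(image); w <- ncol(image)
  stopifnot(h >= 3, w >= 3)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  nb <- lapply(offs, function(d)
    image[2:(h - 1) + d[1], 2:(w - 1) + d[2], drop = FALSE])
  # cyclic differences I7-I0, I6-I7, ..., I0-I1 weighted 2^7 .. 2^0
  code <- array(0, dim(nb[[1]]))
  idx <- c(8:1)                       # I7, I6, ..., I0 (1-based: nb[[8]] = I7)
  prv <- c(1, 8:2)                    # I0, I7, ..., I1
  for (k in 1:8)
    code <- code + (nb[[idx[k]]] - nb[[prv[k]]] >= 0) * 2^(8 - k)
  code <- code - 1
  histo <- tabulate(as.vector(code) + 1L, nbins = 255L)
  feature_vector(histo / sum(histo), paste0("bgc_", 0:254), "bgc")
}
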