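# Local descriptors: HOG, SIFT-style keypoints + bag-of-visual-words.

#' Histogram of oriented gradients features
#'
#' The image is padded to square with a flat background fill (its median
#' intensity), resized to 256 x 256, and decomposed into cells of 32 x 32
#' pixels (an 8 x 8 grid). For each cell a 9-bin unsigned-orientation
#' histogram of gradient magnitudes is accumulated (central-difference
#' gradients, orientations folded to `[0, 180)` degrees, hard bin
#' assignment, no block normalization), and the 64 cell histograms are
#' concatenated row-major into a 576-dimensional vector.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param cell_px Cell side in pixels (default 32).
#' @param n_bins Orientation bins over 180 degrees (default 9).
#' @return Named numeric vector of length `(256/cell_px)^2 * n_bins`
#'   (attribute `group` = `"hog"`).
#' @export
hog_features <- function(image, cell_px = 32, n_bins = 9) {
  assert_gray_image(image)
  h <- nrow(image); w <- ncol(image)
  side <- max(h, w)
  sq <- matrix(stats::median(image), side, side)
  r0 <- floor((side - h) / 2); c0 <- floor((side - w) / 2)
  sq[r0 + seq_len(h), c0 + seq_len(w)] <- image
  img <- t(EBImage::resize(EBImage::Image(t(sq)), 256, 256)@.Data)
  gx <- array(0, c(256, 256)); gy <- array(0, c(256, 256))
  gy[2:255, ] <- (img[3:256, ] - img[1:254, ]) / 2   # gradient down rows
  gx[, 2:255] <- (img[, 3:256] - img[, 1:254]) / 2   # gradient across cols
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180           # unsigned orientation
  bin <- pmin(floor(ang / (180 / n_bins)), n_bins - 1)
  grid <- 256 %/% cell_px
  cell_r <- (row(img) - 1) %/% cell_px
  cell_c <- (col(img) - 1) %/% cell_px
  idx <- cell_r * grid * n_bins + cell_c * n_bins + bin + 1
  out <- numeric(grid^2 * n_bins)
  acc <- tapply(mag, idx, sum)
  out[as.integer(names(acc))] <- acc
  nms <- as.vector(t(outer(
    sprintf("c%d_%d", rep(seq_len(grid), each = grid), rep(seq_len(grid), grid)),
    paste0("o", seq_len(n_bins) - 1), paste, sep = "_")))
  feature_vector(out, nms, "hog")
}

# ---- SIFT-style keypoints ------------------------------------------------

# Difference-of-Gaussians keypoint detection on one octave of 6 scales.
# Returns a matrix (row, col, sigma) of per-level spatial local extrema of
# the DoG above `thresh` times the image dynamic range, strongest first.
# Descriptors are not rotation-normalized.
detect_keypoints <- function(image, n_scales = 6, sigma0 = 1.6,
                             thresh = 0.015, max_keypoints = 80) {
  assert_gray_image(image)
  rng <- diff(range(image))
  if (rng == 0) return(matrix(0, 0, 3, dimnames = list(NULL, c("row", "col", "sigma"))))
  img <- image / 255
  sigmas <- sigma0 * 2^((seq_len(n_scales) - 1) / 3)
  blurred <- lapply(sigmas, function(s)
    t(EBImage::gblur(EBImage::Image(t(img)), sigma = s)@.Data))
  dogs <- lapply(seq_len(n_scales - 1), function(i) blurred[[i + 1]] - blurred[[i]])
  h <- nrow(img); w <- ncol(img)
  if (h < 19 || w < 19)
    return(matrix(0, 0, 3, dimnames = list(NULL, c("row", "col", "sigma"))))
  kps <- list()
  rr <- 9:(h - 9); cc <- 9:(w - 9)   # descriptor support stays inside
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (s in 2:(length(dogs) - 1)) {
    D <- dogs[[s]]
    ctr <- D[rr, cc]
    is_max <- abs(ctr) > thresh * rng / 255
    is_min <- is_max
    for (k in seq_len(nrow(offs))) {
      nb <- D[rr + offs$dr[k], cc + offs$dc[k]]
      is_max <- is_max & (ctr > nb)
      is_min <- is_min & (ctr < nb)
    }
    cand <- which(is_max | is_min, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    cand <- cbind(row = cand[, 1] + 8, col = cand[, 2] + 8)
    kps[[length(kps) + 1]] <- cbind(cand, sigma = sigmas[s],
                                    score = abs(D[cand]))
  }
  if (length(kps) == 0)
    return(matrix(0, 0, 3, dimnames = list(NULL, c("row", "col", "sigma"))))
  kp <- do.call(rbind, kps)
  kp <- kp[order(-kp[, "score"]), , drop = FALSE]
  kp <- kp[seq_len(min(nrow(kp), max_keypoints)), , drop = FALSE]
  kp[, c("row", "col", "sigma"), drop = FALSE]
}

# 128-dimensional gradient-orientation descriptor of a 16x16 patch around a
# keypoint: 4x4 subregions x 8 orientation bins, magnitude-weighted, unit
# normalized with 0.2 clipping.
describe_keypoint <- function(image, r, c) {
  patch <- image[(r - 8):(r + 7), (c - 8):(c + 7)]
  gy <- rbind(patch[2, ] - patch[1, ],
              (patch[3:16, ] - patch[1:14, ]) / 2,
              patch[16, ] - patch[15, ])
  gx <- cbind(patch[, 2] - patch[, 1],
              (patch[, 3:16] - patch[, 1:14]) / 2,
              patch[, 16] - patch[, 15])
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  obin <- pmin(floor(ang / (pi / 4)), 7)
  sub_r <- (row(patch) - 1) %/% 4
  sub_c <- (col(patch) - 1) %/% 4
  idx <- sub_r * 32 + sub_c * 8 + obin + 1
  d <- numeric(128)
  acc <- tapply(mag, idx, sum)
  d[as.integer(names(acc))] <- acc
  n <- sqrt(sum(d^2))
  if (n > 0) { d <- pmin(d / n, 0.2); d <- d / sqrt(sum(d^2)) }
  d
}

# All keypoint descriptors of an image, one row per keypoint.
keypoint_descriptors <- function(image, ...) {
  kp <- detect_keypoints(image, ...)
  if (nrow(kp) == 0) return(matrix(0, 0, 128))
  t(apply(kp, 1, function(k) describe_keypoint(image, k[1], k[2])))
}

#' Build a bag-of-visual-words codebook by k-means
#'
#' Clusters keypoint descriptors into `K` codewords with Lloyd's k-means
#' started from k-means++ seeds; the result is deterministic given the seed.
#' The codebook must be trained on training-split descriptors only to avoid
#' test-set leakage.
#'
#' @param descriptors Numeric matrix, one 128-dim descriptor per row (at
#'   least `K` rows).
#' @param K Number of codewords (default 100).
#' @param seed Integer seed.
#' @param max_descriptors Cap on the number of descriptors used for
#'   clustering; larger sets are subsampled deterministically.
#' @return A `codebook` object with `centers` (`K x 128`), `K` and `seed`.
#' @export
build_codebook <- function(descriptors, K = 100, seed = 1,
                           max_descriptors = 5000) {
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < K)
    stop(sprintf("need >= %d descriptors to build a %d-word codebook; use a smaller K",
                 K, K))
  with_seed(seed, {
    if (nrow(descriptors) > max_descriptors)
      descriptors <- descriptors[sample(nrow(descriptors), max_descriptors), ,
                                 drop = FALSE]
    # k-means++ seeding
    n <- nrow(descriptors)
    centers <- matrix(0, K, ncol(descriptors))
    centers[1, ] <- descriptors[sample(n, 1), ]
    d2 <- rowSums((descriptors - matrix(centers[1, ], n, ncol(descriptors),
                                        byrow = TRUE))^2)
    if (K > 1) for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- descriptors[sample(n, 1, prob = p), ]
      nd <- rowSums((descriptors - matrix(centers[k, ], n, ncol(descriptors),
                                          byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
    km <- suppressWarnings(
      stats::kmeans(descriptors, centers = centers, iter.max = 50,
                    algorithm = "Lloyd"))
    structure(list(centers = km$centers, K = K, seed = seed),
              class = "codebook")
  })
}

#' Bag-of-visual-words histogram of an image
#'
#' Detects keypoints, computes their descriptors, assigns each to its nearest
#' codeword (Euclidean distance, ties to the lowest index) and returns the
#' raw count histogram over the codebook. An image with no detectable
#' keypoints yields the all-zero vector. The histogram total equals the
#' number of detected keypoints and is invariant to keypoint enumeration
#' order.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param codebook A [build_codebook()] result.
#' @param descriptors Optional precomputed descriptor matrix for the image
#'   (skips detection).
#' @return Named numeric vector of length `codebook$K` (attribute `group` =
#'   `"sift"`).
#' @export
sift_bow_features <- function(image = NULL, codebook, descriptors = NULL) {
  stopifnot(inherits(codebook, "codebook"))
  if (is.null(descriptors)) descriptors <- keypoint_descriptors(image)
  K <- codebook$K
  histo <- numeric(K)
  if (nrow(descriptors) > 0) {
    cc <- rowSums(codebook$centers^2)
    dd <- rowSums(descriptors^2)
    cross <- descriptors %*% t(codebook$centers)
    d2 <- outer(dd, cc, "+") - 2 * cross
    assign <- max.col(-d2, ties.method = "first")
    histo <- tabulate(assign, nbins = K)
  }
  feature_vector(histo, paste0("word_", seq_len(K)), "sift")
}
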