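# Geometric/grayscale features and morphological granulometry.

# Ordered outer contour of the largest component, as (row, col) 1-based
# matrix. EBImage::ocontour walks the boundary pixels in order.
outer_contour <- function(mask) {
  main <- largest_component(mask)
  oc <- EBImage::ocontour(EBImage::Image(main * 1))[[1]]
  cbind(row = oc[, 1] + 1, col = oc[, 2] + 1)
}

# Perimeter of an ordered pixel contour: sum of step lengths (1 or sqrt 2),
# closing the loop.
contour_perimeter <- function(pts) {
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  sum(d)
}

# Convex hull of a point set; returns hull vertices in order.
hull_points <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Feret diameters (min/max caliper width) from hull vertices.
feret_diameters <- function(hull) {
  n <- nrow(hull)
  if (n < 2) return(c(max = 0, min = 0))
  dmax <- max(stats::dist(hull))
  widths <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]; b <- hull[i %% n + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- (hull[, 1] - a[1]) * nrm[1] + (hull[, 2] - a[2]) * nrm[2]
    diff(range(proj))
  }, 0)
  c(max = dmax, min = min(widths))
}

# Raw spatial moment m_pq of a weight field over foreground pixels.
raw_moment <- function(r, c, wgt, p, q) sum((r^p) * (c^q) * wgt)

# Hu's seven moment invariants plus normalized second-order central moments,
# computed on the foreground intensity field.
intensity_moment_invariants <- function(img, mask) {
  w <- img * mask
  r <- row(img); c <- col(img)
  m00 <- sum(w)
  if (m00 <= 0) return(rep(0, 10))
  rc <- sum(r * w) / m00; cc <- sum(c * w) / m00
  mu <- function(p, q) sum(((r - rc)^p) * ((c - cc)^q) * w)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(n20, n02, n11, h1, h2, h3, h4, h5, h6, h7)
}

#' Geometric and grayscale features (43 elements)
#'
#' Size and shape measurements of the foreground object together with
#' grayscale statistics over the foreground, as one 43-dimensional vector:
#' 25 geometric elements (area, filled area, convex area, convex rate,
#' perimeter, convex perimeter, circularity \eqn{4\pi A/P^2}, eccentricity,
#' elongation, major/minor axis lengths, equivalent diameter, extent,
#' solidity, orientation as sine/cosine, bounding-box aspect, Feret max/min/
#' ratio, Euler number, hole count, hole-area fraction, boundary roughness,
#' radial-distance dispersion), 8 grayscale statistics (sum, mean, standard
#' deviation, min, max, median, skewness, kurtosis) and 10 normalized
#' central / Hu-style moment invariants of the foreground intensity.
#'
#' Shape measurements use the largest 8-connected component; grayscale
#' statistics use every foreground pixel.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param mask Logical foreground mask of the same shape.
#' @return Named numeric vector of length 43 (attribute `group` =
#'   `"geometric_grayscale"`).
#' @export
geometric_grayscale_features <- function(image, mask) {
  assert_gray_image(image)
  assert_mask(mask, image)
  if (!any(mask)) stop("mask has no foreground object")
  main <- largest_component(mask)
  area <- sum(main)
  filled <- EBImage::fillHull(EBImage::Image(main * 1))@.Data > 0
  filled_area <- sum(filled)
  pts <- which(main, arr.ind = TRUE)
  ctr <- outer_contour(main)
  hull <- hull_points(ctr)
  # +1-pixel-width correction so a filled square's hull area equals its area
  convex_area <- polygon_area(hull) + contour_perimeter(hull) / 2 + 1
  perim <- contour_perimeter(ctr)
  convex_perim <- contour_perimeter(hull)
  circularity <- 4 * pi * area / max(perim^2, .Machine$double.eps)
  # second-order central moments of the binary shape
  rc <- colMeans(pts)
  mu20 <- mean((pts[, 1] - rc[1])^2); mu02 <- mean((pts[, 2] - rc[2])^2)
  mu11 <- mean((pts[, 1] - rc[1]) * (pts[, 2] - rc[2]))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(max(l1, 0)); minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
  elong <- if (minor > 0) major / minor else 1
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  eqd <- sqrt(4 * area / pi)
  bb <- apply(pts, 2, range)
  bb_h <- diff(bb[, 1]) + 1; bb_w <- diff(bb[, 2]) + 1
  extent <- area / (bb_h * bb_w)
  solidity <- filled_area / convex_area
  convex_rate <- area / convex_area
  bb_aspect <- max(bb_h, bb_w) / min(bb_h, bb_w)
  fer <- feret_diameters(hull)
  holes <- filled & !main
  hole_lab <- components8(holes)
  hole_count <- max(hole_lab)
  euler <- 1 - hole_count                 # single component minus holes
  hole_frac <- sum(holes) / filled_area
  roughness <- perim / max(convex_perim, .Machine$double.eps)
  rad <- sqrt((ctr[, 1] - rc[1])^2 + (ctr[, 2] - rc[2])^2)
  radial_disp <- if (mean(rad) > 0) stats::sd(rad) / mean(rad) else 0
  g <- image[mask]
  gray <- c(sum(g), mean(g), stats::sd(g), min(g), max(g), stats::median(g),
            e1071::skewness(g), e1071::kurtosis(g))
  mom <- intensity_moment_invariants(image, mask)
  feature_vector(
    c(area, filled_area, convex_area, convex_rate, perim, convex_perim,
      circularity, ecc, elong, major, minor, eqd, extent, solidity,
      sin(orient), cos(orient), bb_aspect, fer["max"], fer["min"],
      fer["max"] / max(fer["min"], 1), euler, hole_count, hole_frac,
      roughness, radial_disp, gray, mom),
    c("area", "filled_area", "convex_area", "convex_rate", "perimeter",
      "convex_perimeter", "circularity", "eccentricity", "elongation",
      "major_axis", "minor_axis", "equiv_diameter", "extent", "solidity",
      "orientation_sin", "orientation_cos", "bbox_aspect", "feret_max",
      "feret_min", "feret_ratio", "euler_number", "hole_count",
      "hole_area_fraction", "boundary_roughness", "radial_dispersion",
      "gray_sum", "gray_mean", "gray_sd", "gray_min", "gray_max",
      "gray_median", "gray_skewness", "gray_kurtosis",
      paste0("moment_", 1:10)),
    "geometric_grayscale")
}

#' Structuring-element size setups for granulometry
#'
#' Two fixed rosters of flat-disk diameters: setup 1 increases from 2 to 50
#' at interval 4 (13 sizes), setup 2 from 5 to 60 at interval 5 (12 sizes).
#'
#' @param setup 1 or 2.
#' @return Increasing integer vector of disk diameters in pixels.
#' @export
granulometry_sizes <- function(setup = 1) {
  if (setup == 1) seq(2L, 50L, by = 4L) else seq(5L, 60L, by = 5L)
}

# Opening of a binary mask by the Euclidean disk of diameter d, via two
# distance transforms (erosion: interior distance > d/2; dilation: distance
# to the eroded set <= d/2). A 1-pixel background pad makes off-image pixels
# count as background.
disk_opening <- function(mask, d) {
  r <- d / 2
  if (r < 1) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask * 1
  dm <- EBImage::distmap(EBImage::Image(pad))@.Data
  er <- dm > r
  if (!any(er)) return(array(FALSE, dim(mask)))
  dm2 <- EBImage::distmap(EBImage::Image(1 - er * 1))@.Data
  op <- dm2 <= r
  op[2:(h + 1), 2:(w + 1)]
}

#' Granulometric size distribution of a binary mask
#'
#' Opens the mask with flat disks of increasing diameter and reports, for each
#' size, the fraction of foreground pixels removed:
#' \eqn{F_B(\lambda) = 1 - v(\Psi_\lambda(B)) / v(B)}, where
#' \eqn{\Psi_\lambda(B)} is the opening of \eqn{B} by the disk of diameter
#' \eqn{\lambda} and \eqn{v} counts foreground pixels. The curve is
#' nondecreasing in the element size and reaches 1 once the disk exceeds the
#' largest inscribed disk of the object.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @param sizes Increasing vector of disk diameters, e.g.
#'   [granulometry_sizes()].
#' @param group Group label stored on the result.
#' @return Named numeric vector of \eqn{F_B} values in `[0, 1]`, one per size.
#' @export
granulometry_curve <- function(mask, sizes = granulometry_sizes(1),
                               group = "granulometry1") {
  assert_mask(mask)
  if (!any(mask)) stop("mask has no foreground object")
  stopifnot(all(diff(sizes) > 0), all(sizes >= 1))
  v0 <- sum(mask)
  vals <- vapply(sizes, function(d) 1 - sum(disk_opening(mask, d)) / v0, 0)
  feature_vector(vals, paste0("F_", sizes), group)
}
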