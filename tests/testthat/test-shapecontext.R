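# Boundary sampling, inner distances, context histograms, shape matching.

square_mask <- function(side = 40, pad = 5) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

test_that("boundary sampling of a square lands on corners and midpoints", {
  mk <- square_mask(40)
  sh <- sample_boundary(mk, 8)
  expect_equal(nrow(sh$points), 8)
  lo <- 6; hi <- 45; mid <- (lo + hi) / 2
  targets <- rbind(c(lo, lo), c(lo, mid), c(lo, hi), c(mid, hi), c(hi, hi),
                   c(hi, mid), c(hi, lo), c(mid, lo))
  # every target corner/midpoint has a sample within ~1 px
  for (t in seq_len(nrow(targets))) {
    d <- sqrt(rowSums((sh$points - matrix(targets[t, ], 8, 2, byrow = TRUE))^2))
    expect_lt(min(d), 1.5)
  }
  expect_true(all(diag(sh$distance) == 0))
})

test_that("inner distance equals straight-line distance on convex shapes", {
  sh <- sample_boundary(square_mask(30), 20)
  eu <- as.matrix(dist(sh$points))
  expect_true(all(abs(sh$distance - eu) <= 1 + 1e-9))
  expect_true(all(sh$distance - eu >= -1e-9))  # inner >= euclidean
})

test_that("inner distance exceeds euclidean across a concavity", {
  # a C-shaped mask: path between the arm tips must go around
  m <- matrix(FALSE, 40, 40)
  m[5:35, 5:12] <- TRUE
  m[5:12, 5:35] <- TRUE
  m[28:35, 5:35] <- TRUE
  sh <- sample_boundary(m, 40)
  eu <- as.matrix(dist(sh$points))
  expect_true(all(sh$distance - eu >= -1e-9))
  expect_gt(max(sh$distance - eu), 5)
})

test_that("context histograms bin all n-1 remaining points", {
  sh <- sample_boundary(square_mask(30), 24)
  H <- idsc_histograms(sh)
  expect_equal(unname(rowSums(H)), rep(23, 24))
  sh2 <- sample_boundary(square_mask(30), 24)
  expect_identical(idsc_histograms(sh2), H)   # identical shapes, identical sets
})

test_that("histograms of a hand-built 4-point shape match manual binning", {
  pts <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  D <- as.matrix(dist(pts))
  ang <- matrix(c(0, 0.5, 1.2, 2.0,
                  0.5, 0, 0.7, 1.4,
                  1.2, 0.7, 0, 0.3,
                  2.0, 1.4, 0.3, 0), 4, 4)
  sh <- structure(list(points = pts, distance = D, angle = ang, n = 4),
                  class = "shape_sample")
  H <- idsc_histograms(sh, n_dist = 4, n_angle = 6)
  # manual: relative distance bins on exp-spaced edges, angle bins of pi/3
  mn <- mean(D[row(D) != col(D)])
  edges <- exp(seq(log(0.125), log(2), length.out = 5))
  manual <- matrix(0, 4, 24)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    db <- findInterval(D[i, j] / mn, edges)
    db <- min(max(db, 1), 4) - 1
    ab <- min(floor(ang[i, j] / (2 * pi / 6)), 5)
    k <- db * 6 + ab + 1
    manual[i, k] <- manual[i, k] + 1
  }
  expect_identical(H, manual)
})

test_that("match cost is the chi-squared/2 statistic", {
  expect_equal(match_cost(c(2, 0), c(0, 2)), 2)
  expect_equal(match_cost(c(3, 1, 0), c(3, 1, 0)), 0)
  a <- withr::with_seed(1, runif(10)); b <- withr::with_seed(2, runif(10))
  expect_equal(match_cost(a, b), match_cost(b, a))
  expect_equal(match_cost(a, b), brute_chi2(a, b))
  expect_error(match_cost(1:3, 1:4), "bin counts")
})

test_that("shape distance is zero for identical and 90-degree rotated shapes", {
  mk <- square_mask(40)
  sh <- sample_boundary(mk, 16)
  expect_equal(shape_distance(sh, sh), 0)
  rot <- t(mk[nrow(mk):1, ])
  expect_lt(shape_distance(sh, sample_boundary(rot, 16)), 1e-6)
})

test_that("shape distance is invariant to translation and exact scaling", {
  mk <- square_mask(30)
  sh <- sample_boundary(mk, 16)
  shifted <- matrix(FALSE, 60, 60)
  idx <- which(mk, arr.ind = TRUE)
  shifted[cbind(idx[, 1] + 12, idx[, 2] + 7)] <- TRUE
  expect_lt(shape_distance(sh, sample_boundary(shifted, 16)), 1e-9)
  scaled <- sh
  scaled$points <- sh$points * 2.6
  scaled$distance <- sh$distance * 2.6
  expect_lt(shape_distance(sh, scaled), 1e-3)
})

test_that("DP matching equals exhaustive enumeration at small n", {
  for (s in 1:3) {
    C <- withr::with_seed(s, matrix(runif(25, 0, 1), 5, 5))
    expect_equal(planktonmkl:::dp_match_cost(C, 0.3), brute_match(C, 0.3),
                 tolerance = 1e-12)
  }
  Cr <- withr::with_seed(9, matrix(runif(20), 4, 5))   # unequal sizes
  expect_equal(planktonmkl:::dp_match_cost(Cr, 0.25), brute_match(Cr, 0.25),
               tolerance = 1e-12)
})

test_that("shape distances order square, disk and bar sensibly", {
  sq <- sample_boundary(square_mask(36), 16)
  dk <- local({
    n <- 50; x <- matrix(seq_len(n), n, n) - (n + 1) / 2
    sample_boundary((x^2 + t(x)^2) <= 18^2, 16)
  })
  bar <- local({
    m <- matrix(FALSE, 60, 60); m[28:33, 6:55] <- TRUE
    sample_boundary(m, 16)
  })
  expect_gt(shape_distance(sq, bar), shape_distance(sq, dk))
})

test_that("idsc features measure distances to 3 templates per category", {
  sps <- class_spec("s", "star", "smooth")
  spd <- class_spec("d", "ellipse", "smooth", aspect = c(0.9, 1))
  star_masks <- lapply(1:4, function(i) generate_image(sps, i)$mask)
  disk_masks <- lapply(1:3, function(i) generate_image(spd, i)$mask)
  lib <- build_template_library(c(star_masks[1:3], disk_masks),
                                rep(c("star", "disk"), each = 3), n = 60)
  v <- idsc_features(star_masks[[4]], lib)
  expect_length(v, 6)
  expect_true(all(v >= 0))
  # a shape identical to a template scores 0 against it
  v1 <- idsc_features(star_masks[[1]], lib)
  expect_equal(unname(v1["star_t1"]), 0)
  # a star is closer to star templates than to disk templates
  expect_lt(mean(v[startsWith(names(v), "star")]),
            mean(v[startsWith(names(v), "disk")]))
})
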