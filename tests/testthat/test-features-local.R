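# HOG, keypoints, codebook, bag-of-visual-words.

test_that("HOG vector is 576-long and zero on constant images", {
  v <- hog_features(matrix(90, 40, 60))
  expect_length(v, 576)
  expect_true(all(v == 0))
})

test_that("a vertical step edge puts all HOG mass in the horizontal-gradient bin", {
  img <- matrix(0, 256, 256)
  img[, 129:256] <- 200          # already square, no resampling
  v <- hog_features(img)
  nz <- v[v > 0]
  expect_gt(length(nz), 0)
  expect_true(all(grepl("_o0$", names(nz))))   # orientation 0 degrees
})

test_that("rotating a gradient image by 90 degrees shifts the orientation bin", {
  img <- matrix(0, 256, 256)
  img[, 129:256] <- 200
  rot <- t(img[nrow(img):1, ])   # 90-degree rotation, still 256x256
  v <- hog_features(img)
  vr <- hog_features(rot)
  expect_equal(sum(vr), sum(v))
  nzr <- vr[vr > 0]
  expect_true(all(grepl("_o4$", names(nzr))))  # 90 degrees falls in bin 4
})

test_that("codebook with K = 1 is the mean descriptor and is seed-stable", {
  d <- withr::with_seed(1, matrix(rnorm(50 * 128), 50, 128))
  cb <- build_codebook(d, K = 1, seed = 3)
  expect_equal(unname(cb$centers[1, ]), unname(colMeans(d)), tolerance = 1e-9)
  cb2 <- build_codebook(d, K = 1, seed = 3)
  expect_identical(cb$centers, cb2$centers)
  expect_error(build_codebook(d[1:5, ], K = 10), "smaller K")
})

test_that("codebook recovers three well-separated descriptor blobs", {
  centers_true <- withr::with_seed(7, matrix(rnorm(3 * 128, sd = 5), 3, 128))
  d <- withr::with_seed(8, {
    do.call(rbind, lapply(1:3, function(i)
      matrix(rnorm(40 * 128, mean = rep(centers_true[i, ], each = 40),
                   sd = 0.01), 40, 128)))
  })
  cb <- build_codebook(d, K = 3, seed = 1)
  blob_means <- do.call(rbind, lapply(1:3, function(i)
    colMeans(d[(i - 1) * 40 + 1:40, ])))
  # every learned center sits within 0.1 of one generating blob mean
  for (k in 1:3) {
    dists <- sqrt(rowSums((blob_means - matrix(cb$centers[k, ], 3, 128,
                                               byrow = TRUE))^2))
    expect_lt(min(dists), 0.1)
  }
})

test_that("bag-of-words histogram counts every keypoint once, order-free", {
  sp <- class_spec("g", "star", "granular")
  img <- preprocess_image(generate_image(sp, 21)$image)$cell
  desc <- planktonmkl:::keypoint_descriptors(img)
  expect_gt(nrow(desc), 10)
  cb <- build_codebook(rbind(desc, desc + 0.01, desc + 0.02), K = 20, seed = 2)
  v <- sift_bow_features(codebook = cb, descriptors = desc)
  expect_length(v, 20)
  expect_equal(sum(v), nrow(desc))
  perm <- withr::with_seed(3, sample(nrow(desc)))
  v2 <- sift_bow_features(codebook = cb, descriptors = desc[perm, ])
  expect_identical(unname(v), unname(v2))
})

test_that("a blank image has no keypoints and an all-zero histogram", {
  cb <- build_codebook(withr::with_seed(1, matrix(rnorm(30 * 128), 30, 128)),
                       K = 5, seed = 1)
  v <- sift_bow_features(matrix(128, 64, 64), cb)
  expect_true(all(v == 0))
})
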