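# Gabor, variogram, LBP, BGC texture descriptors.

test_that("gabor bank has 48 filters and yields a 96-long vector", {
  bank <- gabor_bank()
  expect_length(bank$filters, 48)
  v <- gabor_features(matrix(100, 40, 40), bank)
  expect_length(v, 96)
})

test_that("gabor features of an all-zero image are zero", {
  expect_true(all(gabor_features(matrix(0, 32, 32)) == 0))
})

test_that("gabor response to a centered impulse matches direct convolution", {
  img <- matrix(0, 15, 15)
  img[8, 8] <- 1
  bank <- gabor_bank()
  v <- gabor_features(img, bank)
  for (i in c(1, 5)) {   # highest-frequency filters fit the raster
    Q <- Mod(brute_conv_complex(img, bank$filters[[i]]$kernel))
    expect_equal(unname(v[2 * i - 1]), mean(Q), tolerance = 1e-10)
    expect_equal(unname(v[2 * i]), sqrt(mean((Q - mean(Q))^2)),
                 tolerance = 1e-10)
  }
})

test_that("variogram is zero for constant images and h^2/2 on a unit ramp", {
  expect_true(all(variogram_features(matrix(77, 16, 16), lags = c(1, 3)) == 0))
  ramp <- matrix(rep(0:15, times = 16), 16, 16, byrow = TRUE)  # I(x, y) = col
  for (h in c(2, 4))
    expect_equal(as.numeric(variogram_features(ramp, lags = h, directions = 0)),
                 h^2 / 2)
})

test_that("variogram equals the brute-force pair enumeration", {
  img <- withr::with_seed(9, matrix(runif(256, 0, 255), 16, 16))
  got <- as.numeric(variogram_features(img, lags = 3))
  expected <- brute_variogram(img, list(c(0, 3), c(3, 0), c(3, 3), c(3, -3)))
  expect_equal(got, expected, tolerance = 1e-9)
  expect_error(variogram_features(img, lags = 16), "extent")
})

test_that("LBP of a constant image is a point mass at code 255 per cell", {
  v <- lbp_features(matrix(128, 20, 20), grid = 2)
  expect_length(v, 4 * 256)
  nz <- v[v > 0]
  expect_true(all(grepl("_b255$", names(nz))))
  expect_equal(sum(v), 18 * 18)   # every interior pixel binned once
})

test_that("LBP histogram equals per-pixel manual codes on a 5x5 image", {
  img <- withr::with_seed(2, matrix(sample(0:255, 25), 5, 5))
  v <- lbp_features(img, grid = 1)
  codes <- c()
  for (r in 2:4) for (c in 2:4) codes <- c(codes, brute_lbp_code(img, r, c))
  manual <- tabulate(codes + 1, nbins = 256)
  expect_equal(as.numeric(v), manual)
})

test_that("BGC1 is a normalized 255-bin histogram with ties coding 254", {
  v <- bgc1_features(matrix(50, 10, 10))
  expect_length(v, 255)
  expect_equal(sum(v), 1)
  expect_equal(unname(v["bgc_254"]), 1)
})

test_that("BGC1 code of an explicit 3x3 patch matches bit enumeration", {
  patch <- matrix(c(1, 8, 7, 2, 0, 6, 3, 4, 5), 3, 3)  # [[1,2,3],[8,0,4],[7,6,5]]
  code <- brute_bgc1_code(patch)
  v <- bgc1_features(patch)
  expect_equal(unname(v[paste0("bgc_", code)]), 1)
})

test_that("LBP and BGC1 are invariant to strictly monotone remapping", {
  img <- withr::with_seed(4, matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  lut <- withr::with_seed(5, cumsum(runif(256, 0.01, 1)))  # strictly increasing
  remapped <- matrix(lut[img + 1], 20, 20)
  remapped <- remapped / max(remapped) * 255
  expect_identical(unname(lbp_features(img)), unname(lbp_features(remapped)))
  expect_identical(unname(bgc1_features(img)), unname(bgc1_features(remapped)))
})
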