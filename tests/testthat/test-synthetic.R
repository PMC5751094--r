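# Synthetic plankton image generator.

test_that("generation is bit-identical for the same spec and seed", {
  sp <- class_spec("t", "chain", "striped")
  expect_identical(generate_image(sp, 42), generate_image(sp, 42))
  expect_false(identical(generate_image(sp, 42), generate_image(sp, 43)))
})

test_that("an ellipse renders with its analytic area", {
  sp <- class_spec("e", "ellipse", "smooth", size = c(40, 40),
                   aspect = c(0.5, 0.5))
  g <- generate_image(sp, 3)
  expect_lt(abs(sum(g$mask) - pi * 20 * 10) / (pi * 20 * 10), 0.05)
})

test_that("marine snow stays below the removal threshold and the mask is recoverable", {
  for (s in c(1, 2)) {
    for (fam in c("ellipse", "star", "ring")) {
      sp <- class_spec("t", fam, "striped")
      g <- generate_image(sp, s)
      raw <- binarize(g$image)
      areas <- sort(flood_fill_areas(raw), decreasing = TRUE)
      expect_true(all(areas[-1] < 5))          # every speckle under 5 px
      rec <- preprocess_image(g$image)$mask
      iou <- sum(rec & g$mask) / sum(rec | g$mask)
      expect_gte(iou, 0.95)
    }
  }
})

test_that("no generated object touches the image border", {
  specs <- default_class_specs()[1:5]
  for (i in seq_along(specs)) {
    m <- generate_image(specs[[i]], 100 + i)$mask
    expect_false(any(m[1, ]) || any(m[nrow(m), ]) ||
                   any(m[, 1]) || any(m[, ncol(m)]))
  }
})

test_that("datasets have the declared size, templates and manifest", {
  ds <- generate_dataset(5, 6, seed = 7)
  expect_length(ds$images, 30)
  expect_equal(sum(ds$manifest$is_template), 15)
  expect_equal(length(ds$template_idx), 15)
  expect_identical(sort(unique(ds$labels)), sort(ds$classes))
  expect_identical(ds$manifest$class, ds$labels)
  ds2 <- generate_dataset(5, 6, seed = 7)
  expect_identical(ds$images, ds2$images)
  expect_error(generate_dataset(99, 6, seed = 1), "roster")
})

test_that("datasets round-trip through the directory-per-class layout", {
  ds <- generate_dataset(2, 6, seed = 3)
  dir <- file.path(tempdir(), "ds_roundtrip")
  unlink(dir, recursive = TRUE)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_dataset(dir)
  expect_identical(back$classes, sort(ds$classes))  # roster is alphabetical
  expect_identical(sort(back$labels), sort(ds$labels))
  expect_length(back$images, 12)
  # ground-truth masks survive exactly; images to 8-bit precision
  j <- match(ds$manifest$id[1], back$manifest$id)
  expect_identical(dim(back$images[[j]]), dim(ds$images[[1]]))
  expect_identical(back$masks[[j]], ds$masks[[1]])
  expect_lt(max(abs(back$images[[j]] - ds$images[[1]])), 0.51)
})

test_that("load_dataset warns on stray files and errors on bad roots", {
  ds <- generate_dataset(2, 6, seed = 4)
  dir <- file.path(tempdir(), "ds_stray")
  unlink(dir, recursive = TRUE)
  write_dataset(ds, dir)
  writeLines("not an image", file.path(dir, ds$classes[1], "README.txt"))
  expect_warning(load_dataset(dir), "skipping")
  expect_error(load_dataset(file.path(tempdir(), "nope_missing")), "exist")
})

test_that("star and ellipse classes separate in template shape distance", {
  star <- class_spec("s", "star", "smooth")
  ell <- class_spec("e", "ellipse", "smooth")
  star_sh <- lapply(1:4, function(i)
    sample_boundary(generate_image(star, i)$mask, 50))
  ell_sh <- lapply(1:4, function(i)
    sample_boundary(generate_image(ell, 10 + i)$mask, 50))
  within <- mean(c(shape_distance(star_sh[[1]], star_sh[[2]]),
                   shape_distance(star_sh[[3]], star_sh[[4]]),
                   shape_distance(ell_sh[[1]], ell_sh[[2]]),
                   shape_distance(ell_sh[[3]], ell_sh[[4]])))
  between <- mean(c(shape_distance(star_sh[[1]], ell_sh[[1]]),
                    shape_distance(star_sh[[2]], ell_sh[[2]]),
                    shape_distance(star_sh[[3]], ell_sh[[3]])))
  expect_gt(between, within)
})
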