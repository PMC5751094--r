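#' Define a synthetic plankton class
#'
#' A class specification pairs a silhouette family with a texture family and
#' parameter ranges. The five silhouette families (ellipse, chain-of-disks,
#' star, appendaged-blob, ring) emulate the morphological diversity seen
#' across plankton imaging devices: elongated diatom-like cells, chains,
#' radiating protists, appendaged zooplankton and ring-shaped colonies. The
#' texture families (smooth, striped, granular) give the texture descriptors
#' class-specific signal.
#'
#' @param name Class name (used as directory / label).
#' @param silhouette One of `"ellipse"`, `"chain"`, `"star"`, `"blob"`,
#'   `"ring"`.
#' @param texture One of `"smooth"`, `"striped"`, `"granular"`.
#' @param size Two-element range of the object's major dimension in pixels.
#' @param aspect Two-element range of the minor/major axis ratio (used by the
#'   ellipse family; other families derive their parameters from `size`).
#' @return A `class_spec` list.
#' @export
class_spec <- function(name, silhouette, texture,
                       size = c(48, 72), aspect = c(0.35, 0.6)) {
  silhouette <- match.arg(silhouette, c("ellipse", "chain", "star", "blob", "ring"))
  texture <- match.arg(texture, c("smooth", "striped", "granular"))
  stopifnot(length(size) == 2, size[1] <= size[2], size[1] >= 8,
            length(aspect) == 2, aspect[1] <= aspect[2])
  structure(list(name = name, silhouette = silhouette, texture = texture,
                 size = size, aspect = aspect),
            class = "class_spec")
}

#' Default synthetic class roster
#'
#' Fifteen distinct silhouette/texture pairings. The first five (one per
#' silhouette family) form the standard benchmark roster; they are designed so
#' that different feature groups carry the discriminative signal for different
#' class pairs (shape groups separate star from ellipse, texture groups
#' separate striped from granular), which is what a multi-view kernel
#' combination can exploit.
#'
#' @return A list of [class_spec()] objects.
#' @export
default_class_specs <- function() {
  base <- list(
    class_spec("ellipsoid_smooth",  "ellipse", "smooth"),
    class_spec("chain_striped",     "chain",   "striped"),
    class_spec("star_granular",     "star",    "granular"),
    class_spec("appendaged_smooth", "blob",    "smooth"),
    class_spec("ring_striped",      "ring",    "striped"))
  extra_sil <- c("ellipse", "chain", "star", "blob", "ring")
  extra_tex <- c("striped", "granular", "smooth", "granular", "smooth",
                 "granular", "smooth", "striped", "striped", "granular")
  extra <- lapply(seq_along(extra_tex), function(i) {
    sil <- extra_sil[(i - 1L) %% 5L + 1L]
    class_spec(paste0(sil, "_", extra_tex[i], "_", i), sil, extra_tex[i])
  })
  c(base, extra)
}

# Rasterize one silhouette family on an h x w canvas centered at (cy, cx).
# `major` is the full length of the object's largest dimension in pixels.
rasterize_silhouette <- function(silhouette, h, w, cy, cx, major, aspect) {
  ri <- matrix(seq_len(h), h, w)
  ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  y <- ri - cy
  x <- ci - cx
  phi <- runif(1, 0, pi)
  xr <- x * cos(phi) + y * sin(phi)
  yr <- -x * sin(phi) + y * cos(phi)
  if (silhouette == "ellipse") {
    a <- major / 2
    b <- a * runif(1, aspect[1], aspect[2])
    (xr / a)^2 + (yr / b)^2 <= 1
  } else if (silhouette == "chain") {
    k <- sample(4:6, 1)
    r <- major / (2 * (1 + 0.8 * (k - 1)))   # overlapping disks span `major`
    offs <- (seq_len(k) - (k + 1) / 2) * 1.6 * r
    m <- array(FALSE, c(h, w))
    for (o in offs) m <- m | ((xr - o)^2 + yr^2 <= r^2)
    m
  } else if (silhouette == "star") {
    k <- sample(5:7, 1)
    amp <- runif(1, 0.35, 0.5)
    r0 <- major / (2 * (1 + amp))
    th <- atan2(yr, xr)
    d <- sqrt(xr^2 + yr^2)
    d <= r0 * (1 + amp * cos(k * th))
  } else if (silhouette == "blob") {
    r0 <- major / 4
    m <- xr^2 + yr^2 <= r0^2
    np <- sample(3:5, 1)
    angs <- runif(np, 0, 2 * pi)
    for (a in angs) {
      len <- runif(1, 0.8, 1.2) * major / 2
      wd <- runif(1, 5, 7)
      ux <- cos(a); uy <- sin(a)
      t <- pmin(pmax(xr * ux + yr * uy, 0), len)
      dseg <- sqrt((xr - t * ux)^2 + (yr - t * uy)^2)
      m <- m | (dseg <= wd / 2)
    }
    m
  } else {  # ring
    rout <- major / 2
    rin <- rout * runif(1, 0.45, 0.6)
    d2 <- xr^2 + yr^2
    d2 <= rout^2 & d2 > rin^2
  }
}

# Apply a texture family to the foreground pixels.
apply_texture <- function(canvas, mask, texture, base) {
  h <- nrow(canvas); w <- ncol(canvas)
  ri <- matrix(seq_len(h), h, w)
  ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (texture == "smooth") {
    cy <- mean(ri[mask]); cx <- mean(ci[mask])
    d <- sqrt((ri - cy)^2 + (ci - cx)^2)
    tex <- base + 18 * (d / max(d[mask], 1))   # gentle radial shading
  } else if (texture == "striped") {
    phi <- runif(1, 0, pi)
    period <- runif(1, 4, 8)
    tex <- base + 25 * sin(2 * pi * (ri * cos(phi) + ci * sin(phi)) / period)
  } else {  # granular
    tex <- matrix(base, h, w)
    dots <- runif(h * w) < 0.22
    tex[dots] <- tex[dots] + 45
  }
  canvas[mask] <- tex[mask]
  canvas
}

#' Generate one synthetic plankton image
#'
#' Renders the class silhouette with its texture on a bright background, then
#' adds marine-snow speckles (each a connected component of area 1 to 4
#' pixels, i.e. strictly below the 5-pixel denoising threshold) and Gaussian
#' pixel noise. The clean silhouette mask is returned as ground truth; the
#' object never touches the image border, so border-based polarity detection
#' remains valid.
#'
#' @param spec A [class_spec()].
#' @param seed Integer seed; the same `(spec, seed)` pair always regenerates a
#'   bit-identical image.
#' @return A list with `image` (numeric matrix in `[0, 255]`) and `mask`
#'   (logical ground-truth matrix).
#' @export
generate_image <- function(spec, seed) {
  stopifnot(inherits(spec, "class_spec"))
  with_seed(seed, {
    h <- sample(96:144, 1)
    w <- sample(96:144, 1)
    bg <- runif(1, 205, 230)
    base <- runif(1, 50, 85)
    margin <- 14
    major <- runif(1, spec$size[1], spec$size[2])
    major <- min(major, min(h, w) - 2 * margin - 2)
    cy <- h / 2 + runif(1, -4, 4)
    cx <- w / 2 + runif(1, -4, 4)
    mask <- rasterize_silhouette(spec$silhouette, h, w, cy, cx, major, spec$aspect)
    canvas <- matrix(bg, h, w)
    canvas <- apply_texture(canvas, mask, spec$texture, base)
    # marine snow: components of area 1-4 px on the background, kept clear of
    # the object so the ground-truth mask stays recoverable
    dil <- EBImage::dilate(EBImage::Image(mask * 1),
                           EBImage::makeBrush(7, "disc"))@.Data > 0
    n_speck <- sample(8:15, 1)
    for (s in seq_len(n_speck)) {
      for (try in 1:20) {
        r0 <- sample(3:(h - 4), 1); c0 <- sample(3:(w - 4), 1)
        if (any(dil[r0:(r0 + 1), c0:(c0 + 1)])) next
        area <- sample(1:4, 1)
        cells <- sample(4, area)
        dr <- c(0, 1, 0, 1)[cells]; dc <- c(0, 0, 1, 1)[cells]
        canvas[cbind(r0 + dr, c0 + dc)] <- base + runif(1, -10, 10)
        break
      }
    }
    canvas <- canvas + rnorm(h * w, 0, 2.5)
    canvas <- pmin(pmax(canvas, 0), 255)
    list(image = canvas, mask = mask)
  })
}

#' Generate a labeled synthetic plankton dataset
#'
#' Builds `n_classes` classes with distinct silhouette/texture pairings and
#' `n_per_class` images each. The first three images of every class are
#' designated shape templates. Regeneration with the same seed is
#' bit-identical. The standard benchmark used throughout the package is
#' `generate_dataset(5, 60, seed = 7)`.
#'
#' @param n_classes Number of classes (at least 2, at most the roster size).
#' @param n_per_class Images per class (at least 6).
#' @param seed Master integer seed.
#' @param specs Optional list of [class_spec()] overriding the default roster.
#' @param dir Optional directory; when given, the dataset is also written as
#'   `dir/<class>/<id>.png` plus `_mask.png` files and a `manifest.json`.
#' @return A `plankton_dataset` list: `images`, `masks` (lists of matrices),
#'   `labels` (character), `classes`, `template_idx` (indices of designated
#'   templates), `manifest` (tibble), `seed`, `specs`.
#' @export
generate_dataset <- function(n_classes, n_per_class, seed, specs = NULL,
                             dir = NULL) {
  stopifnot(n_classes >= 2, n_per_class >= 6)
  roster <- specs %||% default_class_specs()
  if (n_classes > length(roster))
    stop(sprintf("class roster exhausted: %d classes available", length(roster)))
  roster <- roster[seq_len(n_classes)]
  images <- list(); masks <- list(); labels <- character(0)
  rows <- list()
  idx <- 0L
  for (ci in seq_len(n_classes)) {
    sp <- roster[[ci]]
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      s <- child_seed(seed, ci * 100000 + j)
      g <- generate_image(sp, s)
      images[[idx]] <- g$image
      masks[[idx]] <- g$mask
      labels[idx] <- sp$name
      rows[[idx]] <- tibble::tibble(
        sample = idx, id = sprintf("%s_%03d", sp$name, j), class = sp$name,
        is_template = j <= 3, height = nrow(g$image), width = ncol(g$image),
        seed = s)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  ds <- structure(list(
    images = images, masks = masks, labels = labels,
    classes = vapply(roster, `[[`, "", "name"),
    template_idx = which(manifest$is_template),
    manifest = manifest, seed = seed, specs = roster),
    class = "plankton_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.plankton_dataset <- function(x, ...) {
  cat(sprintf("<plankton_dataset> %d images, %d classes (%s), seed %s\n",
              length(x$images), length(x$classes),
              paste(x$classes, collapse = ", "), format(x$seed)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Layout: `dir/<class>/<id>.png`, `dir/<class>/<id>_mask.png`, and a
#' `manifest.json` recording classes, designated templates, seed and specs.
#'
#' @param dataset A `plankton_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "plankton_dataset"))
  for (cl in dataset$classes)
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images)) {
    row <- dataset$manifest[i, ]
    EBImage::writeImage(EBImage::Image(t(dataset$images[[i]] / 255)),
                        file.path(dir, row$class, paste0(row$id, ".png")))
    EBImage::writeImage(EBImage::Image(t(dataset$masks[[i]] * 1)),
                        file.path(dir, row$class, paste0(row$id, "_mask.png")))
  }
  jsonlite::write_json(list(
    classes = dataset$classes,
    templates = dataset$manifest$id[dataset$manifest$is_template],
    seed = dataset$seed,
    specs = lapply(dataset$specs, unclass)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a directory-per-class image dataset
#'
#' Reads grayscale images organized one directory per category. Color images
#' are converted by channel averaging. Files that are not readable images are
#' skipped with a warning; `*_mask.png` companions are loaded as masks when
#' present. Class roster and sample ordering are alphabetical, hence stable
#' across reloads.
#'
#' @param root Dataset root directory.
#' @return A `plankton_dataset` (masks may contain `NULL` entries when no
#'   ground-truth mask files exist).
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset root `%s` does not exist", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 2) stop(sprintf("`%s` must contain >= 2 class directories", root))
  images <- list(); masks <- list(); labels <- character(0); rows <- list()
  idx <- 0L
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl), full.names = TRUE))
    files <- files[!grepl("_mask\\.[A-Za-z]+$", files)]
    if (length(files) == 0) stop(sprintf("class directory `%s` is empty", cl))
    j <- 0L
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
      if (is.null(img)) { warning(sprintf("skipping non-image file `%s`", f)); next }
      dat <- img@.Data
      if (length(dim(dat)) == 3) dat <- apply(dat, c(1, 2), mean)  # luminance avg
      m <- t(dat) * 255
      idx <- idx + 1L; j <- j + 1L
      images[[idx]] <- m
      mf <- sub("\\.[A-Za-z]+$", "_mask.png", f)
      masks[[idx]] <- if (file.exists(mf)) {
        md <- EBImage::readImage(mf)@.Data
        if (length(dim(md)) == 3) md <- md[, , 1]
        t(md) > 0.5
      } else NULL
      labels[idx] <- cl
      rows[[idx]] <- tibble::tibble(
        sample = idx, id = sub("\\.[A-Za-z]+$", "", basename(f)), class = cl,
        is_template = j <= 3, height = nrow(m), width = ncol(m), seed = NA_real_)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  structure(list(images = images, masks = masks, labels = labels,
                 classes = classes, template_idx = which(manifest$is_template),
                 manifest = manifest, seed = NA, specs = NULL),
            class = "plankton_dataset")
}
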