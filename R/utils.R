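# Internal helpers shared across modules.

# Validate a grayscale image: numeric matrix, intensities in [0, 255].
assert_gray_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  rng <- range(img)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` intensities must be finite and within [0, 255]", arg),
         call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, img = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  if (!is.null(img) && !identical(dim(mask), dim(img)))
    stop("image and mask geometries are incompatible", call. = FALSE)
  invisible(mask)
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# 8-connected component labels (integer matrix, 0 = background).
components8 <- function(mask) {
  label_components8(mask)
}

# Area of each 8-connected component, named by label.
component_areas <- function(mask) {
  lab <- components8(mask)
  tab <- tabulate(lab[lab > 0L])
  stats::setNames(tab, seq_along(tab))
}

# Keep only the largest 8-connected component of a mask.
largest_component <- function(mask) {
  lab <- components8(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

# Named feature vector constructor with finiteness guarantee.
feature_vector <- function(values, names, group) {
  v <- as.numeric(values)
  v[!is.finite(v)] <- 0
  names(v) <- names
  attr(v, "group") <- group
  v
}

# Derive a stream-specific child seed from a master seed (kept below 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}
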