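# End-to-end orchestration: feature extraction with caching, fold-level
# fitting (codebook, templates, selection), training, evaluation, report.

#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline with its default.
#' All randomness is derived from the mandatory `seed`; per-stage child seeds
#' are reported in the result so runs are auditable.
#'
#' @param seed Master integer seed (mandatory).
#' @param groups Feature groups to enable; subset of the ten canonical names.
#' @param classifiers Named list of classifier specs; each a list with
#'   `type` (`"nlmkl"` or `"svm"`) and `families` (kernel families).
#' @param C Soft-margin cost used by all classifiers (default 10).
#' @param protocol,k Cross-validation protocol and fold count.
#' @param selection Wrapper-selection settings (folds, cap, patience,
#'   max_features, C).
#' @param idsc Shape-context settings (n boundary points, distance/angle
#'   bins, occlusion penalty).
#' @param sift Bag-of-words settings (codebook size K, per-image keypoint
#'   cap).
#' @param lbp_grid LBP cells per side.
#' @param mkl NLMKL settings (degree, Lambda, max_iter, tol).
#' @param cache_dir Optional directory for the content-addressed feature
#'   cache.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            groups = canonical_groups(),
                            classifiers = list(
                              nlmkl3 = list(type = "nlmkl",
                                            families = c("gaussian", "polynomial", "linear"))),
                            C = 10,
                            protocol = "kfold", k = 2,
                            selection = list(folds = 3, cap = 64, patience = 3,
                                             max_features = 20, C = 1),
                            idsc = list(n = 100, n_dist = 8, n_angle = 12,
                                        penalty = 0.3),
                            sift = list(K = 100, max_keypoints = 80),
                            lbp_grid = 4,
                            mkl = list(degree = 2, Lambda = 1, max_iter = 50,
                                       tol = 1e-4),
                            cache_dir = NULL) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(all(groups %in% canonical_groups()))
  structure(list(seed = seed, groups = groups, classifiers = classifiers,
                 C = C, protocol = protocol, k = k, selection = selection,
                 idsc = idsc, sift = sift, lbp_grid = lbp_grid, mkl = mkl,
                 cache_dir = cache_dir),
            class = "pipeline_config")
}

#' The ten canonical feature group names
#' @return Character vector.
#' @export
canonical_groups <- function() {
  c("geometric_grayscale", "gabor", "variogram", "lbp", "bgc",
    "granulometry1", "granulometry2", "sift", "hog", "idsc")
}

# Per-image static computation: preprocessing, the eight fold-independent
# feature groups, keypoint descriptors and the boundary shape sample.
compute_image_features <- function(img, config, bank) {
  pre <- preprocess_image(img)
  mask <- pre$mask; cell <- pre$cell
  if (!any(mask)) stop("preprocessing left no foreground")
  list(
    mask = mask,
    geometric_grayscale = geometric_grayscale_features(img, mask),
    gabor = gabor_features(cell, bank),
    variogram = variogram_features(cell),
    lbp = lbp_features(cell, grid = config$lbp_grid),
    bgc = bgc1_features(cell),
    granulometry1 = granulometry_curve(mask, granulometry_sizes(1), "granulometry1"),
    granulometry2 = granulometry_curve(mask, granulometry_sizes(2), "granulometry2"),
    hog = hog_features(cell),
    descriptors = keypoint_descriptors(
      cell, max_keypoints = config$sift$max_keypoints),
    shape = sample_boundary(mask, n = config$idsc$n))
}

#' Extract fold-independent features for a whole dataset
#'
#' Runs preprocessing and the eight per-image feature groups, keypoint
#' descriptors and boundary shape samples for every image. With `cache_dir`
#' set, results are cached content-addressed: the key hashes the image
#' pixels and the extraction parameters, so editing one image invalidates
#' only that image's entry.
#'
#' @param dataset A `plankton_dataset`.
#' @param config A [pipeline_config()].
#' @return A `feature_extraction` list: `static` (named list of
#'   sample-by-feature matrices), `descriptors`, `shapes`, `masks`, `labels`.
#' @export
extract_features <- function(dataset, config) {
  stopifnot(inherits(dataset, "plankton_dataset"))
  bank <- gabor_bank()
  key_params <- config[c("groups", "lbp_grid", "sift", "idsc")]
  per <- lapply(seq_along(dataset$images), function(i) {
    img <- dataset$images[[i]]
    cached <- NULL
    key <- NULL
    if (!is.null(config$cache_dir)) {
      key <- file.path(config$cache_dir,
                       paste0(rlang::hash(list(img, key_params)), ".rds"))
      if (file.exists(key)) cached <- readRDS(key)
    }
    if (is.null(cached)) {
      cached <- tryCatch(compute_image_features(img, config, bank),
                         error = function(e)
                           stop(sprintf("feature extraction failed for sample %d (%s): %s",
                                        i, dataset$manifest$id[i], conditionMessage(e)),
                                call. = FALSE))
      if (!is.null(key)) {
        dir.create(dirname(key), recursive = TRUE, showWarnings = FALSE)
        saveRDS(cached, key)
      }
    }
    cached
  })
  static_names <- c("geometric_grayscale", "gabor", "variogram", "lbp", "bgc",
                    "granulometry1", "granulometry2", "hog")
  static <- lapply(static_names, function(g)
    do.call(rbind, lapply(per, `[[`, g)))
  names(static) <- static_names
  structure(list(static = static,
                 descriptors = lapply(per, `[[`, "descriptors"),
                 shapes = lapply(per, `[[`, "shape"),
                 masks = lapply(per, `[[`, "mask"),
                 labels = dataset$labels),
            class = "feature_extraction")
}

# Template library from precomputed shape samples: first three training
# images of every class.
fold_template_library <- function(shapes, labels, train_idx, config) {
  cats <- sort(unique(labels))
  lib <- lapply(cats, function(cl) {
    idx <- train_idx[labels[train_idx] == cl]
    if (length(idx) < 3)
      stop(sprintf("class `%s` has fewer than 3 training shapes", cl))
    lapply(idx[1:3], function(i)
      idsc_histograms(shapes[[i]], config$idsc$n_dist, config$idsc$n_angle))
  })
  names(lib) <- cats
  structure(list(templates = lib, n = config$idsc$n,
                 n_dist = config$idsc$n_dist, n_angle = config$idsc$n_angle),
            class = "template_library")
}

# Assemble the full feature group set for one fold (codebook and templates
# fitted on the training part only), returning matrices for all samples.
fold_feature_groups <- function(base, train_idx, config, fold_seed) {
  groups <- base$static
  if ("sift" %in% config$groups) {
    train_desc <- do.call(rbind, base$descriptors[train_idx])
    cb <- build_codebook(train_desc, K = config$sift$K,
                         seed = child_seed(fold_seed, 1))
    groups$sift <- do.call(rbind, lapply(base$descriptors, function(d)
      sift_bow_features(codebook = cb, descriptors = d)))
  }
  if ("idsc" %in% config$groups) {
    lib <- fold_template_library(base$shapes, base$labels, train_idx, config)
    groups$idsc <- do.call(rbind, lapply(base$shapes, function(s)
      idsc_features(templates = lib, penalty = config$idsc$penalty,
                    shape = s)))
  }
  groups[intersect(config$groups, names(groups))]
}

#' Run the full classification pipeline
#'
#' Executes preprocessing, feature extraction, stratified cross-validation
#' with per-fold codebook/template fitting and per-group wrapper selection,
#' trains every configured classifier, and reports per-fold and pooled
#' metrics with confusion matrices, the selected-dimension summary and the
#' fully resolved configuration. Reproducible given the configuration seed.
#'
#' @param dataset A `plankton_dataset`.
#' @param config A [pipeline_config()].
#' @param features Optional precomputed [extract_features()] result.
#' @return A `pipeline_report`.
#' @export
run_pipeline <- function(dataset, config, features = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  base <- features %||% extract_features(dataset, config)
  labels <- base$labels
  classes <- sort(unique(labels))
  fold <- make_folds(labels, config$k, child_seed(config$seed, 900))
  test_sets <- if (config$protocol == "holdout") list(which(fold == 2)) else
    lapply(seq_len(config$k), function(f) which(fold == f))
  preds <- lapply(config$classifiers, function(x) character(length(labels)))
  per_fold <- lapply(config$classifiers, function(x) list())
  sel_rows <- list()
  for (fi in seq_along(test_sets)) {
    test_idx <- test_sets[[fi]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    fseed <- child_seed(config$seed, fi)
    groups <- fold_feature_groups(base, train_idx, config, fseed)
    sel <- select_features(lapply(groups, function(g) g[train_idx, , drop = FALSE]),
                           labels[train_idx], seed = child_seed(fseed, 2),
                           folds = config$selection$folds,
                           cap = config$selection$cap,
                           patience = config$selection$patience,
                           max_features = config$selection$max_features,
                           C = config$selection$C)
    groups_sel <- apply_selection(groups, sel)
    # z-score with training statistics
    groups_sel <- lapply(groups_sel, function(g) {
      mu <- colMeans(g[train_idx, , drop = FALSE])
      sg <- apply(g[train_idx, , drop = FALSE], 2, stats::sd)
      sg[sg == 0] <- 1
      scale(g, center = mu, scale = sg)
    })
    sel_rows[[fi]] <- tibble::tibble(
      fold = fi, group = names(sel),
      n_selected = vapply(sel, function(s) length(s$indices), 0L),
      cv_score = vapply(sel, `[[`, 0, "score"))
    for (cn in names(config$classifiers)) {
      cs <- config$classifiers[[cn]]
      tr_groups <- lapply(groups_sel, function(g) g[train_idx, , drop = FALSE])
      te_groups <- lapply(groups_sel, function(g) g[test_idx, , drop = FALSE])
      if (identical(cs$type, "svm")) {
        fit <- train_svm_single(do.call(cbind, tr_groups), labels[train_idx],
                                family = cs$families[1], C = config$C,
                                seed = child_seed(fseed, 3))
        pred <- predict(fit, do.call(cbind, te_groups))
      } else {
        fit <- suppressWarnings(train_nlmkl(
          tr_groups, labels[train_idx], families = cs$families,
          C = config$C, degree = config$mkl$degree,
          Lambda = config$mkl$Lambda, max_iter = config$mkl$max_iter,
          tol = config$mkl$tol, seed = child_seed(fseed, 3)))
        pred <- predict(fit, te_groups)
      }
      preds[[cn]][test_idx] <- pred
      per_fold[[cn]][[fi]] <- metrics(
        confusion_matrix(labels[test_idx], pred, classes))
    }
  }
  evaluated <- sort(unique(unlist(test_sets)))
  results <- lapply(names(config$classifiers), function(cn) {
    pooled <- metrics(confusion_matrix(labels[evaluated],
                                       preds[[cn]][evaluated], classes))
    list(per_fold = per_fold[[cn]], pooled = pooled,
         predictions = preds[[cn]])
  })
  names(results) <- names(config$classifiers)
  structure(list(results = results, selected = dplyr::bind_rows(sel_rows),
                 folds = fold, classes = classes, config = config,
                 labels = labels),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (cn in names(x$results)) {
    g <- glance(x$results[[cn]]$pooled)
    cat(sprintf("  %-10s macro R %.4f | macro 1-P %.4f | macro F %.4f\n",
                cn, g$macro_recall, g$macro_error_rate, g$macro_f_measure))
  }
  invisible(x)
}

#' Pooled macro metrics of every classifier in a report
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return Tibble with one row per classifier.
#' @export
glance.pipeline_report <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$results), function(cn) {
    dplyr::mutate(glance(x$results[[cn]]$pooled), classifier = cn,
                  .before = 1)
  }))
}

#' Long feature table of a feature group set
#'
#' The CSV-friendly contract: one row per (sample, group, feature).
#'
#' @param groups Named list of sample-by-feature matrices.
#' @return Tibble with columns `sample`, `group`, `name`, `value`.
#' @export
feature_table <- function(groups) {
  dplyr::bind_rows(lapply(names(groups), function(g) {
    m <- groups[[g]]
    nm <- colnames(m) %||% paste0("f", seq_len(ncol(m)))
    tibble::tibble(sample = rep(seq_len(nrow(m)), times = ncol(m)),
                   group = g,
                   name = rep(nm, each = nrow(m)),
                   value = as.vector(m))
  }))
}
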