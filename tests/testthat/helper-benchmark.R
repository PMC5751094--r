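# The standard synthetic benchmark (5 classes x 60 images, seed 7, 2-fold
# CV) with the full classifier roster, computed once and shared by the
# system-level tests.

.benchmark_env <- new.env(parent = emptyenv())

benchmark_report <- function() {
  if (is.null(.benchmark_env$report)) {
    ds <- generate_dataset(5, 60, seed = 7)
    cfg <- pipeline_config(seed = 7, classifiers = list(
      nlmkl3 = list(type = "nlmkl",
                    families = c("gaussian", "polynomial", "linear")),
      nlmkl_gaussian = list(type = "nlmkl", families = "gaussian"),
      nlmkl_polynomial = list(type = "nlmkl", families = "polynomial"),
      nlmkl_linear = list(type = "nlmkl", families = "linear"),
      svm_gaussian = list(type = "svm", families = "gaussian"),
      svm_polynomial = list(type = "svm", families = "polynomial"),
      svm_linear = list(type = "svm", families = "linear")))
    .benchmark_env$report <- run_pipeline(ds, cfg)
  }
  .benchmark_env$report
}

macro_recall_of <- function(report, classifier) {
  glance(report$results[[classifier]]$pooled)$macro_recall
}
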