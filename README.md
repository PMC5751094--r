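# planktonmkl

Automatic plankton image classification from multi-view features combined
by nonlinear multiple kernel learning (MKL).

Imaging devices such as flow-cytometer imagers, zooplankton scanners and
towed in-situ cameras generate grayscale plankton images far faster than
taxonomists can label them. No single descriptor family separates tens of
plankton categories: gross shape, boundary structure, interior texture and
local keypoint statistics each discriminate different class pairs. This
package implements a complete classification system around that
observation, for ecologists and image-analysis researchers who need a
classical (non-deep-learning) pipeline that works at the scale of a few
thousand labeled images:

1. **Pre-processing** — Otsu binarization with automatic polarity
   detection, removal of sub-5-pixel "marine snow" components, cell
   extraction with a flat median background fill.
2. **Ten feature groups** — geometric/grayscale measurements (43),
   Gabor filter-bank energies (96), variograms (8), grid local binary
   patterns (4096), binary gradient contours (255), two morphological
   granulometry curves (13 + 12), histograms of oriented gradients (576),
   SIFT-style bag-of-visual-words histograms (100), and inner-distance
   shape context distances to three shape templates per class.
3. **Per-group wrapper feature selection** — sequential forward search
   scored by cross-validated linear-SVM accuracy.
4. **NLMKL classifier** — one base kernel per (group, family) pair over
   linear, polynomial and Gaussian families, combined through the
   degree-2 polynomial

   K_eta = sum over (k_1 + ... + k_p = 2) of
           eta_1^{k_1} ... eta_p^{k_p} (K_1^{k_1} ∘ ... ∘ K_p^{k_p}),
           eta >= 0, ||eta||_2 <= Lambda,

   with entrywise kernel products and weights `eta` learned per
   one-vs-rest problem by alternating exact SVM dual solves with projected
   gradient steps.
5. **Evaluation** — confusion matrices with per-class and macro recall,
   precision, error rate (1 − precision) and F-measure, under stratified
   k-fold or holdout protocols.

A deterministic synthetic plankton image generator (five silhouette
families crossed with three texture families, marine-snow speckles,
varying canvas sizes) makes the whole system testable end-to-end without
any external download.

## Worked example

```r
library(planktonmkl)

ds  <- generate_dataset(n_classes = 3, n_per_class = 12, seed = 5)
cfg <- pipeline_config(seed = 5, classifiers = list(
  nlmkl3 = list(type = "nlmkl", families = c("gaussian", "polynomial", "linear")),
  svm_g  = list(type = "svm",   families = "gaussian")))
rep <- run_pipeline(ds, cfg)
print(rep)
#> <pipeline_report>
#>   nlmkl3     macro R 0.9444 | macro 1-P 0.0556 | macro F 0.9444
#>   svm_g      macro R 0.9167 | macro 1-P 0.0816 | macro F 0.9165
```

Under 2-fold cross-validation on 36 synthetic images, the three-family
NLMKL combination recalls 94.4 % of images macro-averaged over classes
with a 5.6 % error rate (1 − precision), against 91.7 % / 8.2 % for a
Gaussian SVM on the concatenated selected features — the multi-view kernel
combination recovers errors the single kernel makes. `glance(rep)` returns
the same table as a tibble, `tidy(rep$results$nlmkl3$pooled)` the
per-class metrics, and `autoplot(rep$results$nlmkl3$pooled$confusion)` the
confusion heatmap. Fitted models expose their learned kernel weights via
`tidy()`:

```r
m <- train_nlmkl(list(shape = X_shape, texture = X_texture), labels)
tidy(m)     # class / group / family / eta
glance(m)   # size, settings, dual optimum, convergence
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/planktonmkl synth --out data/synth --classes 5 --per-class 60 --seed 7
Rscript inst/cli/planktonmkl preprocess --in data/synth --out data/pre --min-size 5
Rscript inst/cli/planktonmkl run --data data/synth --out results --seed 7
```

`run` accepts any directory-per-class image tree (PNG/TIFF/JPEG; color
images are converted by channel averaging) and writes metrics and
confusion CSVs.
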