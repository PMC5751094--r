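---
title: "Multi-view plankton image classification with nonlinear multiple kernel learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view plankton image classification with nonlinear multiple kernel learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktonmkl)
```

## The problem

Plankton imaging devices — flow-cytometer imagers, flatbed zooplankton
scanners, towed in-situ cameras — produce grayscale images of drifting
organisms at rates that rule out manual identification. Classifying these
images automatically is hard for one model family because the discriminative
signal is spread across *views*: gross size and shape, boundary structure,
interior texture, local keypoint statistics. `planktonmkl` implements a
complete classification system built on that observation: ten feature groups
describe each organism from different views, a wrapper procedure selects the
informative columns within each group, and a nonlinear multiple kernel
learning (MKL) classifier combines one kernel per (group, kernel family)
pair with learned nonnegative weights.

## Pre-processing

Images are thresholded with Otsu's method (the between-class-variance
maximizer on the intensity histogram); it is deterministic and
parameter-free, which matters when three device types share one code path.
Foreground polarity is decided automatically: the intensity class holding
the majority of the one-pixel border frame is declared background, since an
organism is assumed not to fill the frame. Connected components smaller
than 5 pixels are removed (8-connectivity; small speckles of "marine snow"
are rarely organisms), and the cell is extracted by replacing background
with the median masked-out intensity — a flat fill that introduces no
artificial gradient edges into the texture and gradient descriptors
downstream. Using 8- rather than 4-connectivity and the median rather than
zero fill are package choices; the denoising threshold of 5 px is part of
the method.

## The ten feature groups

* **Geometric/grayscale (43)** — 25 shape measurements of the largest
  component (area, convex/filled areas and rates, perimeter, circularity
  $4\pi A/P^2$, axis lengths and eccentricity, Feret diameters, Euler
  number and hole statistics, boundary roughness, radial dispersion), 8
  grayscale statistics over the foreground, and 10 normalized-central /
  Hu-style intensity moment invariants. The roster is fixed in
  `geometric_grayscale_features()`; the count of 43 is a design contract,
  and duplicated formulas are avoided by distinguishing convex rate
  (object area / convex area) from solidity (filled area / convex area).
* **Gabor (96)** — a 6-frequency × 8-orientation complex filter bank,
  $F_k = 0.25/\sqrt2^{\,k}$ cycles/px, $\theta_j = j\pi/8$, constant
  relative bandwidth $\sigma = 0.56/F$. Each response magnitude is
  summarized by mean and population standard deviation. Convolution is FFT
  based with zero padding ("same" linear convolution); filter FFTs are
  cached per image size.
* **Variogram (8)** — $\gamma(h)=\frac{1}{2N(h)}\sum[I(x)-I(x+h)]^2$ at
  lags $h \in \{1,2,3,4,6,8,12,16\}$, averaged over the 0/45/90/135 degree
  directions. The lag roster is a package choice (log-spaced coverage of
  fine-to-coarse texture at these devices' typical object sizes); the
  statistic itself is standard geostatistics.
* **Grid LBP (4096)** — 8-bit local binary pattern codes (neighbor ≥
  center codes a 1, clockwise from top-left), histogrammed per cell of a
  4 × 4 grid and concatenated. The grid gives part-based locality at a
  dimension the selection stage can prune.
* **BGC (255)** — single-loop binary gradient contours: the eight cyclic
  pairwise gradients around each interior pixel binarized and read as an
  8-bit word minus one. The sign function is undefined at zero in the
  defining formula; ties are mapped to 1, the only choice under which the
  code range closes at $[0, 254]$ (an all-zero loop would require a
  strictly cyclic ordering of intensities, which is impossible).
* **Granulometry 1 and 2 (13 + 12)** — removed-area fractions
  $F_B(\lambda) = 1 - v(\Psi_\lambda(B))/v(B)$ after opening the mask with
  flat disks of increasing diameter: 2–50 by 4, and 5–60 by 5. Openings
  are computed exactly as Euclidean-disk openings via two distance
  transforms (erosion: interior distance > r; dilation: distance to the
  eroded set ≤ r) with a one-pixel background pad so off-image pixels count
  as background; this is orders of magnitude faster than kernel scanning
  and agrees with translate-and-fit opening bit for bit (tested).
* **HOG (576)** — the image is padded square with its median intensity,
  resized to 256 × 256 and cut into 32 × 32-pixel cells (an 8 × 8 grid);
  each cell contributes a 9-bin unsigned-orientation histogram of
  central-difference gradient magnitudes, concatenated without block
  normalization. "Decomposed into 32 × 32 cells" is read as the *cell
  size*; the alternative reading (a 32 × 32 grid) would give a 9216-dim
  vector out of scale with the other groups.
* **SIFT bag-of-words (100)** — keypoints from a difference-of-Gaussians
  scale stack (one octave, six scales, per-level spatial extrema above an
  intensity-scaled threshold), described by 128-dim 4 × 4 × 8
  gradient-orientation histograms with SIFT-style clipping and
  renormalization, quantized against a 100-word k-means codebook (k-means++
  seeding, Lloyd iterations, fixed seed) trained on training-fold
  descriptors only. The detector/descriptor is implemented in the package
  and deliberately simple: descriptors are not rotation-normalized and
  sub-pixel refinement is omitted. Histograms are raw counts; scaling is
  left to the classifier stage's z-scoring.
* **IDSC (3 × classes)** — inner-distance shape context. One hundred
  boundary points are sampled equally by arclength; inner distances are
  shortest paths through the shape on the visibility graph of the samples;
  inner angles are tangent-relative departure directions. Per point, a
  log-polar histogram (8 log-distance × 12 angle bins, distances normalized
  by the mean inner distance) counts the other 99 points. Two shapes are
  matched by dynamic programming over order-preserving circular
  correspondences with an occlusion penalty of 0.3 per skipped point,
  minimized over all circular start offsets. The feature vector is the raw
  distance to each of three templates per category (no per-category
  aggregation). Templates are the first three training-fold images of each
  class, so the manual-template protocol runs unattended and without
  test-set leakage.

One numerical choice deserves emphasis: the matching stage evaluates the
$\chi^2/2$ cost on *unit-normalized* context histograms. On raw counts the
cost scale grows with the number of sample points and dwarfs the 0.3 skip
penalty, making "skip everything" the optimal matching for any two distinct
shapes — the distance degenerates to a constant. Normalization puts every
pairwise cost in $[0, 1]$, the regime the penalty value comes from. The
histograms themselves (and `match_cost()`) keep raw counts, so each
histogram still sums to $n - 1$.

## Feature selection

Each group is pruned independently by sequential forward selection scored
with 3-fold stratified CV accuracy of a linear SVM (cost 1) on z-scored
columns: add the best column each step, keep the best subset seen, stop
after three consecutive non-improving steps. High-dimensional groups are
first cut to the top 64 candidates by a one-way ANOVA F score, and the
retained set is capped at 20 columns. The wrapper idea fixes the evaluator
and the search; the two caps are package choices that bound the quadratic
evaluation cost at the problem sizes this package targets — the F-score
pre-ranking removes columns a forward search would never pick anyway.
Selection runs inside each training fold only; fold assignment is derived
deterministically from the seed.

## The classifier

For feature groups $x^m$ and kernel families $f$, one base kernel
$K_{m,f}$ is computed per pair — linear $\langle x, z\rangle$, polynomial
$(\langle x, z\rangle/d + 1)^3$, Gaussian
$\exp(-\lVert x - z\rVert^2 / 2w^2)$ with $w$ set by the median
pairwise-distance heuristic — and trace-normalized so no group's scale
dominates. The combined kernel is the degree-$d$ polynomial combination

$$K_\eta = \sum_{k_1+\cdots+k_p = d} \eta_1^{k_1}\cdots\eta_p^{k_p}\,
K_1^{k_1} \circ \cdots \circ K_p^{k_p}, \qquad \eta \ge 0,\ \lVert\eta\rVert_2 \le \Lambda,$$

with entrywise powers and products (hence PSD), defaulting to $d = 2$,
$\Lambda = 1$. Training alternates, per one-vs-rest binary problem:
(a) solving the soft-margin SVM dual exactly on $K_\eta$ (a quadratic
program, solved by an interior-point method), and (b) a projected gradient
step on $\eta$. The step direction *descends* the dual optimum: by duality
the optimal dual value is inversely related to the attainable margin, so a
kernel aligned with the labels has a *small* dual optimum, and descending
it over the bounded set $\{\eta \ge 0, \lVert\eta\rVert_2 \le \Lambda\}$
up-weights informative kernels. (Ascending it would do the opposite —
converge on the least informative kernel in the feasible set.) A step is
accepted only if the re-solved dual optimum does not increase, so the
sequence of dual optima is monotonically nonincreasing; iteration stops
when it changes by less than $10^{-4}$ or after 50 rounds, whichever comes
first, and a model that hits the cap is returned with a recorded warning.
Each binary problem learns its own $\eta$; multiclass prediction is
one-vs-rest argmax with ties to the lowest class index. The whole procedure
is deterministic given its inputs.

The cost grid $C \in \{1, 10, 100\}$ of the comparison experiments is
accepted verbatim; the pipeline default is $C = 10$.

## Evaluation

Confusion matrices have actual classes in rows and predicted classes in
columns. Per class: recall $R = TP/\text{row sum}$, precision
$P = TP/\text{column sum}$ (zero when the class is never predicted), error
rate $1 - P$, and $F = 2PR/(P+R)$ (zero when $P + R = 0$). Headline
numbers are *macro* (unweighted class means) — robust to the class
imbalance real plankton datasets show — with overall accuracy (the micro
recall) also reported, since either averaging convention is defensible.
Cross-validation is stratified, with codebooks, shape templates and
selection fitted per training fold.

## The synthetic generator

`generate_dataset()` renders labeled plankton-like images: five silhouette
families (ellipse, chain-of-disks, star, appendaged blob, ring) crossed
with three texture families (smooth, striped, granular), at canvas sizes
96–144 px, plus marine-snow speckles of area 1–4 px and Gaussian pixel
noise (sd 2.5) on a bright background. Classes pair silhouettes with
textures so that *different groups carry the signal for different class
pairs* — shape groups separate star from ellipse, texture groups separate
striped from granular — which is precisely the structure a multi-view
kernel combination can exploit. The generator is deterministic per
(spec, seed), objects never touch the border (so border-based polarity
detection is valid), and every speckle stays below the 5-px removal
threshold (so the ground-truth mask is recoverable; tested at IoU ≥ 0.95).

What the generator does **not** emulate: optical blur and illumination
fields of real instruments, partial organisms at the frame edge,
out-of-focus plankton, class imbalance, or intra-class morphological
variation beyond parameter ranges. Passing the synthetic benchmark
therefore demonstrates that the mechanics of the system — every extractor,
the selection, the kernel combination, the evaluation protocol — behave as
designed and that multi-view combination helps when views genuinely
complement each other; it does not certify accuracy figures on any real
instrument's data.

## Problem sizes and numerical details

The standard benchmark used by the tests and the acceptance script is 5
classes × 60 images (seed 7) under 2-fold CV — large enough that every
stage (codebook, templates, ten selections, 30-kernel MKL) runs in its
designed regime, small enough for routine re-runs. Other fixed choices:
QP ridge $10^{-8}$; PSD tolerance $-10^{-8}$ on minimal eigenvalues;
selection ties to the lowest column index; prediction ties to the lowest
class index; the Gaussian width heuristic subsamples at most 200 rows;
codebooks subsample at most 5000 descriptors deterministically. Degenerate
inputs fail loudly: empty masks, single-class labels, non-finite features
and mismatched geometries are errors, not silent repairs; a constant image
binarizes to an empty mask by contract.

## Limitations

The SIFT-style detector is intentionally minimal (no rotation
normalization, single octave); granulometry diameters below 3 px use the
3 × 3 cross as their discrete disk; IDSC cost grows quadratically in
boundary samples and linearly in templates, dominating extraction time at
large class counts; and the system targets tens of classes, not the
hundreds where deep feature learning would be the natural tool.
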