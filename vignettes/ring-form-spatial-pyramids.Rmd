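---
title: "Ring-form spatial pyramids for tumor ROI classification"
author: "ringspm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-form spatial pyramids for tumor ROI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringspm)
```

## The problem and the model

Classifying the pathological type of a segmented lesion from a single 2D
grayscale slice is a standard computer-aided-diagnosis task: the inputs are an
intensity image, a binary tumor mask drawn by a radiologist, and a class label
per slice, with several slices per patient. Global statistics over the mask —
an intensity histogram, gray-level co-occurrence (GLCM) summaries, or a
bag-of-visual-words (BoW) histogram — throw away two kinds of information that
are clinically relevant for brain tumors:

1. **Peritumoral context.** Different tumor types sit against different
   anatomy (meningiomas against skull and CSF, pituitary tumors against the
   sphenoidal sinus), so tissue just *outside* the delineated border is
   informative. The package therefore augments the mask by morphological
   dilation with a discrete disk of radius $R$,
   $\{(\Delta y,\Delta x): \Delta y^2 + \Delta x^2 \le R^2\}$, before any
   feature is computed.
2. **Spatial layout.** Classic spatial pyramid matching (SPM) recovers layout
   by splitting an image into rectangular cells, but rectangles are
   meaningless for lesions of arbitrary shape and size. The package instead
   splits the (augmented) region of interest into **ring-form subregions**:
   each ROI pixel's Euclidean distance to the ROI border is linearly rescaled
   to $[0,1]$, and level $k$ of the pyramid partitions $[0,1]$ into $2^k$
   equal subintervals, giving $2^k$ concentric rings (ring 0 is the
   outermost). Rings at level $k+1$ nest pairwise inside level-$k$ rings,
   which is exactly the structure the pyramid-match kernel requires.

Per-subregion feature vectors are individually normalized, weighted with the
pyramid-match level weights $w_0 = 2^{-L}$ and $w_k = 2^{-(L-k+1)}$ for
$k \ge 1$, and concatenated (level ascending, ring ascending). Classification
uses a support vector machine with the histogram intersection kernel
$K(x,y) = \sum_i \min(x_i, y_i)$, one-vs-one with majority voting, with the
penalty $C$ chosen by patient-grouped inner cross-validation on the training
set. Sparse-representation classification (orthogonal matching pursuit over a
dictionary of training descriptors, class-wise residual rule) and kNN are
provided as baselines.

## Feature families

All families operate on a percentile-normalized slice: the intensities at the
1st and 99th percentiles of the whole slice are mapped to 0 and 1 and the
tails clipped. Clipping (rather than extrapolation) is the robust min-max
convention; the operation is exactly invariant under positive affine maps of
the raw intensities, so scanner gain and offset cancel. Percentiles are taken
over the whole slice by default (`norm_scope = "slice"`), with an ROI-scoped
variant as a config switch.

* **Intensity histogram** — gray levels quantized to $G$ uniform bins on
  $[0,1]$ (top edge closed), counted over the subregion, L1-normalized.
* **GLCM-element** — the isotropic GLCM (average of the four direction count
  matrices at 0°, 45°, 90°, 135°, distance $D$, symmetric counting, one final
  normalization) is itself symmetric, so its lower triangle including the
  diagonal — $G(G+1)/2$ numbers — is used directly as a histogram-style
  feature. Averaging in *count* space rather than probability space keeps the
  estimate stable when directions have unequal pair counts, which is common
  in thin rings.
* **GLCM statistics** — the classical 16-dimensional baseline: contrast,
  correlation, energy and homogeneity from each of the four per-direction
  GLCMs. Correlation is defined as 0 when a marginal variance vanishes, so
  constant rings cannot produce NaN. Because correlation can be negative this
  family violates the HIK nonnegativity contract; the HIK-SVM refuses it and
  kNN is the natural classifier for it.
* **Bag of words** — raw $p \times p$ patches densely sampled at every ROI
  pixel whose full window fits inside the image (no padding is fabricated;
  the window may extend outside the ROI, only the *center* must be an ROI
  pixel). A codebook of $M$ words is learned by k-means (k-means++ seeding,
  Lloyd iterations, empty clusters re-seeded from the farthest points —
  written out explicitly so the result is a pure function of pool order and
  seed) from at most 100&nbsp;000 training-fold descriptors. Coding is either
  hard vector quantization or localized soft assignment over the $k$ nearest
  words with Gaussian weights $\exp(-\lVert x - w\rVert^2 / 2\sigma^2)$,
  $\sigma = 0.5$ by default; the alternative reading of the bandwidth as
  $\exp(-\beta d^2)$ is available as `sa_convention = "beta"`. Pooling is sum
  or max; sum pooling of VQ codes followed by L1 normalization is exactly the
  empirical word-frequency distribution. Patches are assigned to rings by
  their center pixel.

GLCM pairs inside a ring count only when **both** endpoints are ring pixels,
so ring features never depend on pixels outside their ring — the property
that makes per-ring features well-defined under the partition.

## Design choices where the design was open

* *Distance convention*: "border" means the nearest pixel outside the ROI, so
  border-adjacent ROI pixels get distance 1 and background 0; the image is
  treated as padded with background, so a region flush with the image edge is
  bounded by it.
* *Distance rescaling* uses $(d - d_{\min})/(d_{\max} - d_{\min})$ over ROI
  pixels; subintervals are half-open with the last closed at 1, which
  guarantees an exact partition. A one-pixel-thin ROI (constant distance)
  degenerates to ring 0 with a warning.
* *Order of operations*: dilation precedes partition, so the rings live on
  the augmented region.
* *Pyramid weights* follow the standard pyramid-match telescoping scheme and
  are applied **after** per-subregion normalization; `mode = "single_level"`
  uses only level $L$, unweighted, for ablation studies. Empty rings
  contribute zero blocks rather than being dropped, keeping descriptor length
  constant across slices.
* *SVM details*: the Gram matrix is precomputed and passed to a binary
  C-SVC per class pair; vote ties break by the largest summed signed decision
  value, then the lowest class index. The default $C$ grid is
  $2^{-5}, 2^{-3}, \dots, 2^{15}$.
* *SRC stopping rule*: orthogonal matching pursuit with a fixed sparsity
  level $T$ (default 30); a residual-threshold rule would also be defensible,
  but a fixed $T$ makes runtime and behaviour predictable.
* *kNN ties*: majority vote, then smallest mean distance, then lowest class
  index — every tie is broken deterministically so results are reproducible.

## Evaluation protocol

Patients — not slices — are partitioned into five folds, stratified so the
per-class patient counts per fold differ by at most one (within each class,
patients are shuffled and dealt round-robin, with the starting fold rotated
between classes so overall fold sizes also balance). Slices of one patient
never straddle the train/test divide, and all fold-dependent state (codebook,
$C$, classifier) is fitted per fold on training slices only; the fold indices
flow through the API, so leakage is structurally impossible rather than
merely discouraged. Reports carry per-fold and pooled confusion matrices,
per-class sensitivity and one-vs-rest specificity (percent, one decimal), and
*both* the mean of per-fold accuracies and the pooled accuracy — the two
disagree slightly whenever folds differ in size, so both are kept.
Paired comparisons between configurations reuse identical fold assignments.
2D visualization uses regularized LDA, the top-2 eigenvectors of
$(S_w + \lambda I)^{-1} S_b$ with $\lambda = 10^{-3}\,\mathrm{tr}(S_w)/d$ by
default.

## The phantom generator

No suitable public dataset ships with the package, so a generator produces
phantoms with the *statistical* structure the method exploits, while making
no attempt at anatomical realism. Each slice is a wide-spread smoothed-noise
background, a star-convex tumor (a disk whose polar radius is perturbed by
Fourier harmonics of orders 2–4, rescaled so the area stays near the
unperturbed disk's), a peritumoral annulus, and additive Gaussian noise;
images are written as 16-bit TIFF, masks as 0/255 PNG. Class signal can be
placed independently in three channels:

* `texture_only` — tumor-interior means differ (0.30/0.50/0.70);
* `context_only` — only the annulus offset differs (−0.20/0/+0.20);
* `radial_only` — only the radial layout differs; all three profiles are
  two-valued step functions of the **area-quantile** of border distance with
  exactly 50/50 mass, so whole-ROI histograms are class-identical by
  construction and only ring partition can separate the classes. Two of the
  profiles are monotone (bright-core vs bright-rim); the third is a mid-depth
  band, because only two monotone maps of the quantile share the same
  marginal histogram;
* `null` — identical classes, for chance-level calibration.

One deliberate subtlety: the background spans a wide intensity range
(`background_sd = 0.15` around 0.5), so the slice-level 1st/99th percentile
anchors are pinned by class-independent background tails. Without this, the
brightest class structure would pin the 99th percentile and the min-max
normalization itself would leak (or destroy) class signal. All class
intensities stay strictly inside the background's percentile window.

All randomness flows from one integer seed through per-slice substreams, so a
configuration reproduces byte-identical files on any machine.

What phantoms do **not** emulate: anatomy, MRI physics (bias fields, Rician
noise, partial volume), inter-rater segmentation variability, and the
long-tailed heterogeneity of real tumors. Passing the synthetic experiments
therefore shows that the implementation extracts the kind of signal the
method targets — not that any particular accuracy will transfer to clinical
data.

## Problem sizes and numerical choices

The shipped experiments use 15 patients × 4 slices of 64×64 pixels — large
enough that each fold trains on 48 slices and every ring at $L = 2$ is
populated, small enough for interactive use. The synthetic experiments search
$C$ over $2^{-3}, 2^{-1}, \dots, 2^{9}$ (a subset of the default grid; on
separable phantoms the selection saturates well inside this range). Distances
come from an exact Euclidean distance transform; dilation uses the exact
discrete disk; k-means stops when the largest squared center shift falls
below $10^{-8}$ or after 100 iterations. GLCM symmetry is asserted to
$10^{-9}$ before the lower triangle is read off.

## Worked synthetic experiments

The two experiments mirror the method's qualitative claims and are recomputed
by `scripts/acceptance.R`:

* **Context experiment** (`context_only` phantom): at $R = 0$ the annulus is
  invisible and cross-validated accuracy is statistically indistinguishable
  from the 1/3 chance level; at $R = 8$ (annulus width 6) the context enters
  the ROI and accuracy rises by far more than 15 percentage points.
* **Radial experiment** (`radial_only` phantom): whole-ROI histograms are
  identical across classes, so $L = 0$ performs at chance; $L = 2$ ring
  features separate all three profiles.

Because test slices of one patient are predicted by the same fold model, the
chance-level check uses a binomial interval at the *patient* count, the
independent unit, not the slice count.

## Known limitations

* Features are 2D per-slice; no 3D aggregation across a patient's slices.
* The HIK-SVM requires nonnegative descriptors; of the four families only the
  16-statistic baseline violates this, and it must be paired with kNN.
* Masks are inputs; the package does not segment.
* The inner $C$ search assumes each class has patients in most inner folds;
  with very few patients per class the folds degrade gracefully with a
  warning, but $C$ selection becomes noisy.

## A minimal session

```{r example, eval = FALSE}
dir <- tempfile()
man <- generate_phantom_dataset(
  phantom_config(n_patients = 15, slices_per_patient = 4,
                 classes = phantom_classes("context_only"), seed = 11),
  dir)

cfg <- ringspm_config(feature = "histogram", G = 10, R = 8, L = 2)
fit <- ringspm(man, cfg)
print(fit)
plot(fit)                      # regularized-LDA scatter of the descriptors

cv <- cross_validate(man, cfg, seed = 5)
summary(cv)
write_report(cv, file.path(dir, "report"))
```
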