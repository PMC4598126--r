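# ringspm

Ring-form spatial pyramid matching for classifying segmented regions of
interest (ROIs) in 2D grayscale medical images — built for the brain-tumor
setting (meningioma vs glioma vs pituitary tumor on contrast-enhanced
T1-weighted MRI slices with manually delineated tumor masks), but applicable
to any slice + binary-mask + label dataset.

## The method

Global histogram features over a lesion mask ignore two useful signals:
tissue just *outside* the border, and the lesion's internal spatial layout.
The package addresses both:

1. **ROI augmentation.** The tumor mask is dilated with a discrete disk of
   radius *R* (offsets with Δy² + Δx² ≤ R²), pulling peritumoral context into
   the region of interest.
2. **Ring-form partition.** Each ROI pixel's Euclidean distance to the ROI
   border is rescaled to [0, 1]; level *k* of a pyramid splits [0, 1] into 2ᵏ
   equal subintervals, producing 2ᵏ concentric rings that nest across levels —
   a shape-adaptive replacement for the rectangular grids of classic spatial
   pyramid matching.

Per-ring features — intensity histograms, the lower-triangular elements of
the isotropic gray-level co-occurrence matrix (GLCM-element, G(G+1)/2
values), classical 16-dimensional GLCM statistics, or a raw-patch
bag-of-visual-words histogram over a k-means codebook — are L1/L2-normalized
per ring, weighted with the pyramid-match level weights (w₀ = 2⁻ᴸ,
wₖ = 2⁻⁽ᴸ⁻ᵏ⁺¹⁾), and concatenated. Classification uses a one-vs-one SVM with
the histogram intersection kernel K(x, y) = Σᵢ min(xᵢ, yᵢ), the penalty C
tuned by patient-grouped inner cross-validation; sparse-representation (OMP)
and kNN classifiers are included as baselines. Evaluation is patient-
stratified 5-fold cross-validation with confusion matrices, per-class
sensitivity/specificity and regularized-LDA 2D scatter plots.

A seeded phantom generator produces synthetic datasets whose class signal
lives selectably in the tumor texture, the peritumoral annulus, or the radial
intensity layout, so every stage of the pipeline is testable without any
download. See the vignette in `vignettes/ring-form-spatial-pyramids.Rmd` for
the full methods account.

## Worked example

A phantom whose three classes differ *only* in the intensity of a 6-pixel
peritumoral annulus — invisible to any feature computed on the raw mask, and
recovered by ROI augmentation plus ring partition:

```r
library(ringspm)

dir <- tempfile()
man <- generate_phantom_dataset(
  phantom_config(n_patients = 15, slices_per_patient = 4,
                 classes = phantom_classes("context_only"), seed = 11), dir)
man
#> Slice manifest: 60 slices, 15 patients, 3 classes ( glioma, meningioma, pituitary )

cfg <- ringspm_config(feature = "histogram", G = 10, R = 8, L = 2,
                      C_grid = 2^seq(-3, 9, 2))
fit <- ringspm(man, cfg)
fit
#> Ring-form spatial-pyramid ROI classifier
#>   feature: histogram   R = 8   L = 2   mode = pyramid
#>   classifier: svm   classes: glioma, meningioma, pituitary
#>   trained on 60 slices (15 patients), descriptor length 70
#>   selected C = 0.125

cv <- cross_validate(man, cfg, seed = 5)
summary(cv)
#> 5-fold patient-stratified cross-validation (histogram, R=8, L=2, pyramid)
#>   mean fold accuracy: 100.00%   pooled accuracy: 100.00%
#> Pooled confusion matrix (true rows x predicted columns):
#>            glioma meningioma pituitary
#> glioma         20          0         0
#> meningioma      0         20         0
#> pituitary      0           0        20
```

Descriptor length 70 is (2⁰ + 2¹ + 2²) rings × G = 10 bins. With `R = 0,
L = 0` the same pipeline scores at chance on this dataset (the annulus never
enters the ROI); the gap is the package's core claim in miniature. Setting
`feature = "bow"` switches to the bag-of-words family (patch size `p`,
codebook size `M`); `mode = "single_level"` ablates the multi-level pyramid.

A thin command-line wrapper ships in `inst/cli/ringspm`
(`ringspm synth ...`, `ringspm crossval ...`).

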