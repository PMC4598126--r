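Package: ringspm
Title: Ring-Form Spatial Pyramid Matching for Tumor ROI Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of segmented regions of interest (ROIs) in 2D
    grayscale medical images, built around two ideas: augmenting the tumor
    mask by morphological dilation with a disk so peritumoral context enters
    the feature pool, and splitting the (augmented) ROI into concentric
    ring-form subregions by normalized Euclidean border distance, so that
    spatial-pyramid matching applies to arbitrarily shaped lesions.
    Per-subregion features (intensity histograms, gray-level co-occurrence
    matrix elements and statistics, raw-patch bag-of-visual-words) are
    weighted and concatenated into a pyramid descriptor and classified with a
    histogram-intersection-kernel support vector machine under
    patient-stratified cross-validation. Includes a synthetic phantom
    generator for controlled experiments and sparse-representation and
    k-nearest-neighbour baseline classifiers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    kernlab,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
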