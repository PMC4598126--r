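#' Fit a ring-form spatial-pyramid ROI classifier
#'
#' The package's central fitting function. For every training slice it builds
#' the ring-form spatial-pyramid descriptor prescribed by `config` (dilated
#' ROI, ring partition, per-ring features, SPM weighting), learning any
#' fold-dependent state on the training slices only (the bag-of-words
#' codebook, the SVM penalty C via patient-grouped inner cross-validation),
#' and trains the configured classifier.
#'
#' @param manifest A `slice_manifest`, or a path to a manifest CSV.
#' @param config A `ringspm_config`.
#' @param subset Optional integer indices of the manifest records to train
#'   on (default: all). Slices outside `subset` are never touched during
#'   fitting, which is what makes fold-wise use leak-free.
#' @param slices Optional preloaded list of `annotated_slice` objects
#'   matching the manifest rows (an optimization for repeated fits).
#' @param seed Seed for codebook sampling and inner CV; defaults to
#'   `config$seed`.
#' @return Object of class `ringspm` with `print`, `summary`, `predict` and
#'   `plot` methods.
#' @examples
#' \donttest{
#' dir <- tempfile(); cfg <- phantom_config(n_patients = 6, slices_per_patient = 2)
#' man <- generate_phantom_dataset(cfg, dir)
#' fit <- ringspm(man, ringspm_config(feature = "histogram", G = 10, R = 4, L = 1))
#' predict(fit, man)
#' }
#' @export
ringspm <- function(manifest, config = ringspm_config(), subset = NULL,
                    slices = NULL, seed = config$seed) {
  cl <- match.call()
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  rec <- manifest$records
  if (is.null(subset)) subset <- seq_len(nrow(rec))
  if (is.null(slices)) {
    slices <- vector("list", nrow(rec))
    slices[subset] <- lapply(subset, function(i) load_slice(rec[i, ]))
  }
  train_slices <- slices[subset]
  y <- rec$label[subset]
  patients <- rec$patient_id[subset]
  if (length(unique(y)) < 2) stop_fmt("training subset contains fewer than 2 classes")

  codebook <- NULL
  if (config$feature == "bow") {
    pool <- do.call(rbind, lapply(train_slices, function(s) {
      roi <- augment_roi(s$mask, config$R)
      nm <- normalize_intensity(s$image, config$p_low, config$p_high,
                                mask = if (config$norm_scope == "roi") s$mask else NULL)
      extract_patches(nm, roi, config$p)$descriptors
    }))
    codebook <- build_dictionary(pool, config$M, n_sample = config$n_sample,
                                 seed = seed)
  }

  X <- t(vapply(train_slices,
                function(s) build_descriptor(s, config, codebook)$vector,
                numeric(descriptor_length(config))))

  model <- switch(config$classifier,
    svm = train_svm_ovo(X, y, patients, C_grid = config$C_grid, seed = seed),
    src = src_model(X, y, T_sparsity = config$T_sparsity),
    knn = list(X = X, y = y, k = config$k)
  )
  structure(list(config = config, classes = manifest$classes,
                 codebook = codebook, model = model,
                 X = X, y = y, patients = patients,
                 seed = seed, call = cl),
            class = "ringspm")
}

#' Descriptor length implied by a configuration
#'
#' `(2^(L+1) - 1) * B` in pyramid mode, `2^L * B` in single-level mode, where
#' B is the per-region feature dimension (G for histograms, G(G+1)/2 for
#' GLCM elements, 16 for GLCM statistics, M for bag-of-words).
#'
#' @param config A `ringspm_config`.
#' @return Integer descriptor length.
#' @export
descriptor_length <- function(config) {
  B <- switch(config$feature,
              histogram = config$G,
              glcm_element = config$G * (config$G + 1) / 2,
              glcm_stats16 = 16,
              bow = config$M)
  n_regions <- if (config$mode == "single_level") 2^config$L
               else 2^(config$L + 1) - 1
  as.integer(n_regions * B)
}

#' @export
print.ringspm <- function(x, ...) {
  cat("Ring-form spatial-pyramid ROI classifier\n")
  cat(sprintf("  feature: %s   R = %d   L = %d   mode = %s\n",
              x$config$feature, x$config$R, x$config$L, x$config$mode))
  cat(sprintf("  classifier: %s   classes: %s\n", x$config$classifier,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d slices (%d patients), descriptor length %d\n",
              nrow(x$X), length(unique(x$patients)), ncol(x$X)))
  if (x$config$classifier == "svm") cat(sprintf("  selected C = %g\n", x$model$C))
  invisible(x)
}

#' @export
summary.ringspm <- function(object, ...) {
  print(object)
  pred <- predict(object, object$X)
  cat(sprintf("  training accuracy: %.1f%%\n", 100 * mean(pred == object$y)))
  invisible(object)
}

#' Predict tumor classes for new slices
#'
#' @param object A fitted `ringspm`.
#' @param newdata A `slice_manifest`, a list of `annotated_slice` objects, a
#'   single `annotated_slice`, or a descriptor matrix with columns matching
#'   the training descriptors.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.ringspm <- function(object, newdata, ...) {
  X <- descriptors_for(object, newdata)
  switch(object$config$classifier,
    svm = predict(object$model, X),
    src = vapply(seq_len(nrow(X)),
                 function(i) classify_src(object$model, X[i, ]), character(1)),
    knn = classify_knn(object$model$X, object$model$y, X, object$config$k)
  )
}

descriptors_for <- function(object, newdata) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != ncol(object$X)) {
      stop_fmt("descriptor length %d does not match the fitted model (%d)",
               ncol(newdata), ncol(object$X))
    }
    return(newdata)
  }
  if (inherits(newdata, "annotated_slice")) newdata <- list(newdata)
  if (inherits(newdata, "slice_manifest")) {
    rec <- newdata$records
    newdata <- lapply(seq_len(nrow(rec)), function(i) load_slice(rec[i, ]))
  }
  t(vapply(newdata,
           function(s) build_descriptor(s, object$config, object$codebook)$vector,
           numeric(ncol(object$X))))
}

#' Plot the fitted model's training descriptors in LDA space
#'
#' Projects the training descriptors to 2D with regularized LDA and draws a
#' class-colored scatter plot (red, green, blue in sorted class order).
#'
#' @param x A fitted `ringspm`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [lda_project_2d()] result.
#' @export
plot.ringspm <- function(x, ...) {
  proj <- lda_project_2d(x$X, x$y)
  cols <- c("red", "green3", "blue")[match(x$y, x$classes)]
  graphics::plot(proj$coords, col = cols, pch = 19,
                 xlab = "LDA 1", ylab = "LDA 2",
                 main = "Training descriptors, regularized LDA projection", ...)
  graphics::legend("topright", legend = x$classes, col = c("red", "green3", "blue"),
                   pch = 19, bty = "n")
  invisible(proj)
}
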