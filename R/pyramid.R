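# Assembly of the final ring-form spatial-pyramid descriptor.

#' Pipeline configuration
#'
#' Validated parameter set for the full descriptor + classifier pipeline.
#' Defaults follow the configuration that performed best in the CE-MRI
#' brain-tumor experiments this package is built around: dilation radius
#' R = 8, gray levels G = 20, co-occurrence distance D = 4, 5x5 patches,
#' 300-word codebook, VQ coding, sum pooling, L1 normalization, HIK-SVM.
#'
#' @param feature Feature family: `"histogram"`, `"glcm_element"`,
#'   `"glcm_stats16"` or `"bow"`.
#' @param R ROI dilation radius in pixels.
#' @param L Maximum pyramid level (2^k rings at level k).
#' @param mode `"pyramid"` (all levels, SPM-weighted) or `"single_level"`
#'   (level L only, unweighted).
#' @param G Gray levels for quantization.
#' @param D GLCM co-occurrence distance.
#' @param p Patch side length (odd) for bag-of-words.
#' @param M Codebook size.
#' @param coding `"vq"` or `"sa_k"`.
#' @param k_nn Neighbours for SA-k coding.
#' @param sigma SA-k Gaussian bandwidth.
#' @param sa_convention `"sigma"` or `"beta"` bandwidth reading.
#' @param pooling `"sum"` or `"max"`.
#' @param norm Per-region normalization: `"l1"` or `"l2"`.
#' @param classifier `"svm"`, `"src"` or `"knn"`.
#' @param C_grid SVM penalty grid searched by inner cross-validation.
#' @param T_sparsity OMP sparsity level for SRC.
#' @param k Neighbours for the kNN classifier.
#' @param n_folds Outer cross-validation folds.
#' @param n_sample Descriptor sample cap for codebook learning.
#' @param p_low,p_high Intensity normalization percentiles.
#' @param norm_scope Percentile scope: `"slice"` (whole slice) or `"roi"`.
#' @param seed Integer seed for all randomized steps.
#' @return Object of class `ringspm_config` (a validated named list).
#' @export
ringspm_config <- function(feature = c("histogram", "glcm_element", "glcm_stats16", "bow"),
                           R = 8, L = 0, mode = c("pyramid", "single_level"),
                           G = 20, D = 4, p = 5, M = 300,
                           coding = c("vq", "sa_k"), k_nn = 5, sigma = 0.5,
                           sa_convention = c("sigma", "beta"),
                           pooling = c("sum", "max"), norm = c("l1", "l2"),
                           classifier = c("svm", "src", "knn"),
                           C_grid = 2^seq(-5, 15, by = 2),
                           T_sparsity = 30, k = 1, n_folds = 5,
                           n_sample = 100000, p_low = 1, p_high = 99,
                           norm_scope = c("slice", "roi"), seed = 1) {
  cfg <- list(
    feature = match.arg(feature), R = as.integer(R), L = as.integer(L),
    mode = match.arg(mode), G = as.integer(G), D = as.integer(D),
    p = as.integer(p), M = as.integer(M), coding = match.arg(coding),
    k_nn = as.integer(k_nn), sigma = sigma,
    sa_convention = match.arg(sa_convention),
    pooling = match.arg(pooling), norm = match.arg(norm),
    classifier = match.arg(classifier), C_grid = C_grid,
    T_sparsity = as.integer(T_sparsity), k = as.integer(k),
    n_folds = as.integer(n_folds), n_sample = as.integer(n_sample),
    p_low = p_low, p_high = p_high, norm_scope = match.arg(norm_scope),
    seed = as.integer(seed)
  )
  if (cfg$R < 0) stop_fmt("R must be >= 0")
  if (cfg$L < 0) stop_fmt("L must be >= 0")
  if (cfg$G < 2) stop_fmt("G must be >= 2")
  if (cfg$D < 1) stop_fmt("D must be >= 1")
  if (cfg$p < 3 || cfg$p %% 2 == 0) stop_fmt("p must be odd and >= 3")
  if (cfg$M < 2) stop_fmt("M must be >= 2")
  if (length(cfg$C_grid) == 0 || any(cfg$C_grid <= 0)) stop_fmt("C_grid must be positive")
  if (cfg$n_folds < 2) stop_fmt("n_folds must be >= 2")
  structure(cfg, class = "ringspm_config")
}

#' Update a configuration
#'
#' Replace named fields of a `ringspm_config`, re-validating the result.
#' Unknown keys are rejected.
#'
#' @param config A `ringspm_config`.
#' @param ... Fields to replace.
#' @return A new `ringspm_config`.
#' @export
update_config <- function(config, ...) {
  changes <- list(...)
  unknown <- setdiff(names(changes), names(config))
  if (length(unknown) > 0) {
    stop_fmt("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  args <- unclass(config)
  args[names(changes)] <- changes
  do.call(ringspm_config, args)
}

#' @export
print.ringspm_config <- function(x, ...) {
  cat(sprintf("ringspm config: feature=%s R=%d L=%d mode=%s classifier=%s\n",
              x$feature, x$R, x$L, x$mode, x$classifier))
  if (x$feature %in% c("histogram", "glcm_element", "glcm_stats16"))
    cat(sprintf("  G=%d D=%d\n", x$G, x$D))
  if (x$feature == "bow")
    cat(sprintf("  p=%d M=%d coding=%s pooling=%s\n", x$p, x$M, x$coding, x$pooling))
  invisible(x)
}

#' Spatial-pyramid level weights
#'
#' The pyramid-match kernel level weights: level 0 gets 1 / 2^L and level
#' k >= 1 gets 1 / 2^(L - k + 1), so finer levels count more and the
#' telescoped sum over levels reproduces the pyramid match kernel.
#'
#' @param L Maximum level (>= 0).
#' @return Numeric vector of length L + 1 (weights for levels 0..L).
#' @examples
#' spm_weights(2)  # 1/4, 1/4, 1/2
#' @export
spm_weights <- function(L) {
  L <- as.integer(L)
  if (L < 0) stop_fmt("L must be >= 0")
  if (L == 0) return(1)
  c(1 / 2^L, 1 / 2^(L - seq_len(L) + 1))
}

# Feature vector for one subregion, by family.
region_feature <- function(family, ring, quantized, normalized, patches, codes,
                           config) {
  switch(family,
    histogram = intensity_histogram(quantized, ring),
    glcm_element = {
      g <- glcm_isotropic(quantized, ring, D = config$D)
      if (!g$normalized) numeric(config$G * (config$G + 1) / 2)
      else glcm_element_features(g)
    },
    glcm_stats16 = {
      suppressWarnings(glcm_statistics_16(quantized, ring, D = config$D))
    },
    bow = {
      if (is.null(patches)) return(numeric(config$M))
      inside <- ring[patches$centers]
      pool_codes(codes[inside, , drop = FALSE], config$pooling, M = config$M)
    }
  )
}

#' Build the ring-form spatial-pyramid descriptor of one slice
#'
#' Runs the full per-slice feature pipeline: percentile normalization,
#' quantization (for histogram/GLCM families), ROI augmentation by disk
#' dilation, ring partition of the augmented region, per-subregion feature
#' extraction, per-subregion normalization, SPM level weighting, and
#' concatenation in (level ascending, ring ascending) order. In
#' `single_level` mode only level L is used, unweighted.
#'
#' @param slice An `annotated_slice` (or list with `image` and `mask`).
#' @param config A `ringspm_config`.
#' @param codebook A `codebook`; required iff `config$feature == "bow"`.
#' @return Object of class `region_descriptor`: list with `vector` (the
#'   descriptor), `layout` (data.frame: level, ring, start, length) and
#'   `config`.
#' @export
build_descriptor <- function(slice, config, codebook = NULL) {
  if (config$feature == "bow" && is.null(codebook)) {
    stop_fmt("the bag-of-words feature family requires a codebook")
  }
  nm_mask <- if (config$norm_scope == "roi") slice$mask else NULL
  normalized <- normalize_intensity(slice$image, config$p_low, config$p_high,
                                    mask = nm_mask)
  roi <- augment_roi(slice$mask, config$R)
  part <- ring_partition(roi, config$L)
  quantized <- NULL
  if (config$feature %in% c("histogram", "glcm_element", "glcm_stats16")) {
    quantized <- quantize(normalized, config$G)
  }
  patches <- NULL; codes <- NULL
  if (config$feature == "bow") {
    patches <- extract_patches(normalized, roi, config$p)
    codes <- if (config$coding == "vq") encode_vq(patches$descriptors, codebook)
             else encode_sa_k(patches$descriptors, codebook, config$k_nn,
                              config$sigma, config$sa_convention)
  }
  levels_used <- if (config$mode == "single_level") config$L else 0:config$L
  weights <- spm_weights(config$L)
  blocks <- list(); layout <- list()
  pos <- 0L
  for (k in levels_used) {
    w <- if (config$mode == "single_level") 1 else weights[k + 1]
    rings <- part$levels[[k + 1]]
    for (i in seq_along(rings)) {
      f <- region_feature(config$feature, rings[[i]], quantized, normalized,
                          patches, codes, config)
      f <- normalize_vec(f, config$norm) * w
      blocks[[length(blocks) + 1]] <- f
      layout[[length(layout) + 1]] <- data.frame(level = k, ring = i - 1L,
                                                 start = pos + 1L,
                                                 length = length(f))
      pos <- pos + length(f)
    }
  }
  structure(list(vector = unlist(blocks, use.names = FALSE),
                 layout = do.call(rbind, layout),
                 config = config),
            class = "region_descriptor")
}
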