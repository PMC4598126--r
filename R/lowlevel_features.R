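# Histogram and GLCM feature extractors over arbitrary subregion masks.
# Co-occurring pairs are counted only when BOTH endpoints lie inside the
# subregion, so ring features never depend on pixels outside their ring.

#' Normalized intensity histogram over a region
#'
#' Counts quantized gray levels over the region's pixels and L1-normalizes to
#' sum 1. An empty region yields the all-zero vector (no normalization).
#'
#' @param levels A `quantized_slice` or an integer matrix of levels in `0..G-1`.
#' @param region Logical mask of the same shape.
#' @param G Number of gray levels (taken from `levels` when it is a
#'   `quantized_slice`).
#' @return Numeric vector of length `G`.
#' @export
intensity_histogram <- function(levels, region, G = NULL) {
  if (inherits(levels, "quantized_slice")) {
    if (is.null(G)) G <- levels$G
    levels <- levels$levels
  }
  if (is.null(G)) stop_fmt("G must be supplied when levels is a plain matrix")
  region <- as_logical_mask(region)
  v <- levels[region]
  if (length(v) == 0) return(numeric(G))
  counts <- tabulate(v + 1L, nbins = G)
  counts / sum(counts)
}

# The four GLCM direction offsets (dy, dx) at distance D: 0, 45, 90, 135 deg.
glcm_offsets <- function(D) {
  list(c(0, D), c(-D, D), c(-D, 0), c(-D, -D))
}

# Symmetric co-occurrence counts for one direction: ordered pairs (p, p+off)
# with both pixels in the region, accumulated as (i,j) and (j,i).
glcm_direction_counts <- function(levels, region, G, dy, dx) {
  nr <- nrow(levels); nc <- ncol(levels)
  y0 <- max(1L, 1L - dy); y1 <- min(nr, nr - dy)
  x0 <- max(1L, 1L - dx); x1 <- min(nc, nc - dx)
  P <- matrix(0, G, G)
  if (y0 > y1 || x0 > x1) return(P)
  A <- levels[y0:y1, x0:x1, drop = FALSE]
  B <- levels[(y0 + dy):(y1 + dy), (x0 + dx):(x1 + dx), drop = FALSE]
  keep <- region[y0:y1, x0:x1, drop = FALSE] &
          region[(y0 + dy):(y1 + dy), (x0 + dx):(x1 + dx), drop = FALSE]
  if (!any(keep)) return(P)
  code <- A[keep] * G + B[keep]          # 0-based (i, j) pair code
  counts <- tabulate(code + 1L, nbins = G * G)
  C <- matrix(counts, G, G, byrow = TRUE) # row i = first pixel's level
  C + t(C)
}

#' Isotropic gray-level co-occurrence matrix
#'
#' Symmetric GLCM averaged over the four directions 0, 45, 90 and 135
#' degrees at co-occurrence distance `D`. Direction count matrices are
#' averaged in count space, then L1-normalized once; if the region admits no
#' pixel pair at all, the zero matrix is returned with `normalized = FALSE`.
#'
#' @param levels A `quantized_slice` or integer matrix of levels in `0..G-1`.
#' @param region Logical mask; only pairs with both pixels inside count.
#' @param G Gray levels (>= 2); defaults to the `quantized_slice`'s G.
#' @param D Co-occurrence distance in pixels (>= 1).
#' @return Object of class `glcm`: list with `P` (G x G matrix), `G`, `D`,
#'   `normalized` flag.
#' @export
glcm_isotropic <- function(levels, region, G = NULL, D = 1) {
  if (inherits(levels, "quantized_slice")) {
    if (is.null(G)) G <- levels$G
    levels <- levels$levels
  }
  if (is.null(G) || G < 2) stop_fmt("G must be >= 2")
  if (D < 1) stop_fmt("co-occurrence distance D must be >= 1")
  region <- as_logical_mask(region)
  total <- matrix(0, G, G)
  for (off in glcm_offsets(as.integer(D))) {
    total <- total + glcm_direction_counts(levels, region, G, off[1], off[2])
  }
  P <- total / 4
  s <- sum(P)
  if (s == 0) {
    return(structure(list(P = P, G = G, D = D, normalized = FALSE), class = "glcm"))
  }
  structure(list(P = P / s, G = G, D = D, normalized = TRUE), class = "glcm")
}

#' Lower-triangular GLCM elements as a feature vector
#'
#' The histogram-style feature family that uses the symmetric GLCM's lower
#' triangle (including the diagonal) directly, in row-major order
#' P(0,0), P(1,0), P(1,1), P(2,0), ... — length G(G+1)/2.
#'
#' @param glcm A `glcm` object (or symmetric matrix).
#' @return Numeric vector of length `G * (G + 1) / 2`.
#' @export
glcm_element_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$P else glcm
  if (max(abs(P - t(P))) > 1e-9) stop_fmt("GLCM is not symmetric")
  G <- nrow(P)
  out <- numeric(G * (G + 1) / 2)
  pos <- 1L
  for (i in seq_len(G)) {       # row-major over the lower triangle
    for (j in seq_len(i)) {
      out[pos] <- P[i, j]
      pos <- pos + 1L
    }
  }
  out
}

#' Second-order (Haralick-style) GLCM statistics
#'
#' Contrast, correlation, energy and homogeneity of a normalized GLCM.
#' Correlation is defined as 0 when either marginal standard deviation
#' vanishes (constant regions), so degenerate rings never produce NaN.
#'
#' @param glcm A normalized, nonzero `glcm` object.
#' @return Named numeric vector `c(contrast, correlation, energy, homogeneity)`.
#' @export
glcm_statistics <- function(glcm) {
  if (!inherits(glcm, "glcm") || !isTRUE(glcm$normalized)) {
    stop_fmt("glcm_statistics() requires a normalized GLCM")
  }
  P <- glcm$P
  G <- glcm$G
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mui <- sum((0:(G - 1)) * pi_); muj <- sum((0:(G - 1)) * pj_)
  sdi <- sqrt(sum((0:(G - 1) - mui)^2 * pi_))
  sdj <- sqrt(sum((0:(G - 1) - muj)^2 * pj_))
  correlation <- if (sdi * sdj == 0) 0 else
    sum((i - mui) * (j - muj) * P) / (sdi * sdj)
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

#' 16 per-direction GLCM statistics
#'
#' The four Haralick-style statistics from each of the four per-direction
#' (symmetric, individually normalized) GLCMs, concatenated in direction
#' order 0, 45, 90, 135 degrees — 16 texture features per region. A direction
#' with no valid pixel pair contributes zeros with a warning.
#'
#' @inheritParams glcm_isotropic
#' @return Numeric vector of length 16.
#' @export
glcm_statistics_16 <- function(levels, region, G = NULL, D = 1) {
  if (inherits(levels, "quantized_slice")) {
    if (is.null(G)) G <- levels$G
    levels <- levels$levels
  }
  if (is.null(G) || G < 2) stop_fmt("G must be >= 2")
  region <- as_logical_mask(region)
  out <- numeric(0)
  for (off in glcm_offsets(as.integer(D))) {
    C <- glcm_direction_counts(levels, region, G, off[1], off[2])
    s <- sum(C)
    if (s == 0) {
      warn_fmt("direction (%d,%d) has no co-occurring pairs; its 4 features set to 0",
               off[1], off[2])
      out <- c(out, numeric(4))
    } else {
      g <- structure(list(P = C / s, G = G, D = D, normalized = TRUE), class = "glcm")
      out <- c(out, glcm_statistics(g))
    }
  }
  unname(out)
}
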