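#' Percentile-based intensity normalization
#'
#' Robust min-max scaling to \[0, 1\]: the intensities at the `p_low` and
#' `p_high` percentiles (linear interpolation between order statistics) are
#' computed, the image is shifted and scaled so they map to 0 and 1, and
#' values outside the percentile window are clipped. By default percentiles
#' are taken over the whole slice; pass a mask to restrict them to the ROI.
#'
#' @param image Numeric matrix of nonnegative intensities.
#' @param p_low,p_high Percentiles in \[0, 100\] (defaults 1 and 99).
#' @param mask Optional logical matrix; when given, percentiles are computed
#'   over masked pixels only (the whole image is still rescaled).
#' @return Object of class `normalized_slice`: list with `values` (matrix in
#'   \[0,1\]), `p_low_value`, `p_high_value`.
#' @examples
#' normalize_intensity(matrix(0:99, 10, 10))
#' @export
normalize_intensity <- function(image, p_low = 1, p_high = 99, mask = NULL) {
  if (length(image) == 0) stop_fmt("cannot normalize an empty image")
  if (!(p_low < p_high)) stop_fmt("p_low must be < p_high")
  pool <- if (is.null(mask)) image else image[mask]
  qs <- stats::quantile(pool, probs = c(p_low, p_high) / 100, names = FALSE, type = 7)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) {
    warn_fmt("degenerate slice: P%g == P%g == %g; all normalized values set to 0",
             p_low, p_high, lo)
    values <- array(0, dim = dim(image))
  } else {
    values <- pmin(pmax((image - lo) / (hi - lo), 0), 1)
    dim(values) <- dim(image)
  }
  structure(list(values = values, p_low_value = lo, p_high_value = hi),
            class = "normalized_slice")
}

#' Uniform gray-level quantization
#'
#' Maps normalized intensities in \[0, 1\] to integer levels `0..G-1` using
#' `G` equal bins with the top edge closed: `level = min(floor(v * G), G - 1)`.
#'
#' @param normalized A `normalized_slice` or a numeric matrix in \[0, 1\].
#' @param G Number of gray levels (>= 2).
#' @return Object of class `quantized_slice`: list with `levels` (integer
#'   matrix in `0..G-1`) and `G`.
#' @examples
#' quantize(matrix(c(0, 0.55, 1), 1, 3), G = 10)$levels
#' @export
quantize <- function(normalized, G) {
  if (!is.numeric(G) || length(G) != 1 || G < 2) {
    stop_fmt("G must be a single integer >= 2 (got %s)", paste(G, collapse = ","))
  }
  v <- if (inherits(normalized, "normalized_slice")) normalized$values else normalized
  if (any(v < 0 | v > 1)) stop_fmt("quantize() expects values in [0, 1]")
  lev <- pmin(floor(v * G), G - 1)
  storage.mode(lev) <- "integer"
  dim(lev) <- dim(v)
  structure(list(levels = lev, G = as.integer(G)), class = "quantized_slice")
}
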