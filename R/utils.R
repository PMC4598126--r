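#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a base seed and an integer stream id.
# Keeps results < 2^31 so set.seed() accepts them on all platforms.
child_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) + 9973 * (as.numeric(stream) + 1)
  as.integer(s %% 2147483647)
}

# L1/L2 vector normalization with the zero-vector convention used throughout:
# a zero vector is returned unchanged so empty subregions contribute zero blocks.

#' Normalize a nonnegative feature vector
#'
#' Divides by the L1 or L2 norm; a zero vector is returned unchanged (the
#' convention for empty subregions, whose descriptors must stay all-zero).
#'
#' @param v Numeric vector, nonnegative for `"l1"`-normalized histogram use.
#' @param norm Either `"l1"` or `"l2"`.
#' @return Numeric vector of the same length.
#' @examples
#' normalize_vec(c(2, 2), "l1")
#' normalize_vec(c(3, 4), "l2")
#' @export
normalize_vec <- function(v, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  nv <- if (norm == "l1") sum(abs(v)) else sqrt(sum(v^2))
  if (nv == 0) return(v)
  v / nv
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

as_logical_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  m <- mask > 0
  storage.mode(m) <- "logical"
  m
}
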