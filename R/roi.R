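# ROI augmentation and ring-form partition: the spatial scaffold every
# feature family is evaluated on.

#' Disk structuring element
#'
#' The discrete disk of radius `R`: all integer offsets (dy, dx) with
#' dy^2 + dx^2 <= R^2, returned as a (2R+1) x (2R+1) 0/1 kernel matrix.
#'
#' @param R Integer radius >= 0.
#' @return 0/1 numeric matrix.
#' @export
disk_kernel <- function(R) {
  R <- as.integer(R)
  if (R < 0) stop_fmt("disk radius must be >= 0")
  off <- expand.grid(dy = -R:R, dx = -R:R)
  k <- matrix(0, 2 * R + 1, 2 * R + 1)
  inside <- off$dy^2 + off$dx^2 <= R^2
  k[cbind(off$dy[inside] + R + 1, off$dx[inside] + R + 1)] <- 1
  k
}

#' Augment an ROI by disk dilation
#'
#' Morphological dilation of a binary tumor mask with the discrete disk of
#' radius `R`, clipped to the image bounds, so peritumoral context enters the
#' region of interest. `R = 0` is the identity.
#'
#' @param mask Logical matrix (or 0/1), at least one TRUE pixel.
#' @param R Dilation radius in pixels (integer >= 0).
#' @return Logical matrix, a superset of `mask`.
#' @export
augment_roi <- function(mask, R) {
  mask <- as_logical_mask(mask)
  if (!any(mask)) stop_fmt("cannot augment an empty mask")
  R <- as.integer(R)
  if (R < 0) stop_fmt("dilation radius must be >= 0")
  if (R == 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- EBImage::dilate(m, disk_kernel(R)) > 0
  dim(out) <- dim(mask)
  out
}

#' Euclidean distance to the ROI border
#'
#' For each foreground pixel, the shortest Euclidean distance to the nearest
#' background pixel; the image is treated as padded with background outside
#' its bounds, and background pixels get 0. A pixel adjacent to the border
#' therefore has distance 1.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of distances, same shape.
#' @export
border_distance <- function(mask) {
  mask <- as_logical_mask(mask)
  if (!any(mask)) stop_fmt("cannot compute border distance of an empty mask")
  # EBImage::distmap treats out-of-image as foreground; pad with background
  # first so the image boundary acts as ROI border.
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- as.numeric(mask)
  d <- EBImage::distmap(padded, metric = "euclidean")
  out <- d[2:(nr + 1), 2:(nc + 1)]
  dim(out) <- dim(mask)
  out
}

#' Ring-form partition of an ROI
#'
#' Normalizes each ROI pixel's border distance to \[0, 1\] via
#' `(d - dmin) / (dmax - dmin)` over ROI pixels, then at every level
#' `k = 0..L` splits \[0, 1\] into `2^k` equal subintervals (half-open, the
#' last closed at 1). Pixels whose normalized distance falls in subinterval
#' `i` form ring `i`; ring 0 is the outermost (smallest distance). Level 0 is
#' the whole ROI; rings at level k+1 nest pairwise inside level-k rings.
#'
#' @param mask Logical ROI matrix (typically the augmented mask).
#' @param L Maximum pyramid level (integer >= 0).
#' @return Object of class `ring_partition`: list with `levels` (list of
#'   length L+1; element k+1 is a list of `2^k` logical ring masks), `L`, and
#'   `distance_map` (normalized distances; NA outside the ROI).
#' @export
ring_partition <- function(mask, L) {
  mask <- as_logical_mask(mask)
  L <- as.integer(L)
  if (L < 0) stop_fmt("pyramid level L must be >= 0")
  if (!any(mask)) stop_fmt("cannot partition an empty mask")
  d <- border_distance(mask)
  dv <- d[mask]
  dmin <- min(dv); dmax <- max(dv)
  dnorm <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (dmax == dmin) {
    warn_fmt("degenerate ROI (constant border distance): all pixels assigned to ring 0")
    dnorm[mask] <- 0
  } else {
    dnorm[mask] <- (dv - dmin) / (dmax - dmin)
  }
  levels <- vector("list", L + 1)
  for (k in 0:L) {
    nring <- 2^k
    idx <- pmin(floor(dnorm * nring), nring - 1)  # last subinterval closed at 1
    rings <- vector("list", nring)
    for (i in 0:(nring - 1)) {
      r <- !is.na(idx) & idx == i
      dim(r) <- dim(mask)
      rings[[i + 1]] <- r
    }
    levels[[k + 1]] <- rings
  }
  structure(list(levels = levels, L = L, distance_map = dnorm),
            class = "ring_partition")
}

#' @export
print.ring_partition <- function(x, ...) {
  sizes <- vapply(x$levels[[x$L + 1]], sum, numeric(1))
  cat(sprintf("Ring partition, levels 0..%d; finest-level ring sizes: %s\n",
              x$L, paste(sizes, collapse = ", ")))
  invisible(x)
}
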