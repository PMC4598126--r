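# Raw-patch bag-of-visual-words: dense patch extraction, k-means codebook,
# hard (VQ) and localized soft-assignment coding, sum/max pooling.

#' Densely sample raw patches within a region
#'
#' One descriptor per region pixel whose full p x p window lies inside the
#' image bounds (the window may extend outside the region — only the center
#' must be a region pixel; no padding is ever fabricated). Descriptors are
#' the row-major flattened windows of the normalized image.
#'
#' @param normalized A `normalized_slice` or numeric matrix in \[0, 1\].
#' @param region Logical mask of sampling centers.
#' @param p Odd patch side length >= 3.
#' @return Object of class `patch_set`: list with `descriptors` (N x p^2
#'   matrix), `centers` (N x 2 matrix of row/col), `p`.
#' @export
extract_patches <- function(normalized, region, p) {
  v <- if (inherits(normalized, "normalized_slice")) normalized$values else normalized
  p <- as.integer(p)
  if (p < 3 || p %% 2 == 0) stop_fmt("patch size p must be odd and >= 3 (got %d)", p)
  region <- as_logical_mask(region)
  h <- (p - 1L) %/% 2L
  nr <- nrow(v); nc <- ncol(v)
  ok <- region
  ok[c(seq_len(min(h, nr)), seq_len(min(h, nr)) + nr - min(h, nr)), ] <- FALSE
  ok[, c(seq_len(min(h, nc)), seq_len(min(h, nc)) + nc - min(h, nc))] <- FALSE
  centers <- which(ok, arr.ind = TRUE)
  if (nrow(centers) == 0) stop_fmt("no valid patch centers: every region pixel's %dx%d window leaves the image", p, p)
  # row-major flatten: offsets ordered by window row, then window column
  offs <- expand.grid(dx = -h:h, dy = -h:h)[, c("dy", "dx")]
  X <- matrix(0, nrow(centers), p * p)
  for (q in seq_len(p * p)) {
    X[, q] <- v[cbind(centers[, 1] + offs$dy[q], centers[, 2] + offs$dx[q])]
  }
  structure(list(descriptors = X, centers = unname(centers), p = p),
            class = "patch_set")
}

# Squared Euclidean distances between rows of X and rows of W.
sqdist <- function(X, W) {
  d <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  pmax(d, 0)
}

# k-means++ initial centers, deterministic given the seed.
kmeanspp_init <- function(X, M) {
  n <- nrow(X)
  centers <- matrix(0, M, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- sqdist(X, centers[1, , drop = FALSE])[, 1]
  for (m in seq_len(M)[-1]) {
    if (sum(d2) == 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    centers[m, ] <- X[idx, ]
    d2 <- pmin(d2, sqdist(X, centers[m, , drop = FALSE])[, 1])
  }
  centers
}

#' Learn a visual codebook by k-means
#'
#' Samples up to `n_sample` descriptors from the pool without replacement and
#' runs Lloyd's k-means with k-means++ seeding. Empty clusters are re-seeded
#' from the points farthest from their assigned centers, so the codebook
#' always has `M` words. Fully deterministic given the pool order and seed.
#'
#' @param descriptor_pool N x d numeric matrix of training descriptors.
#' @param M Codebook size (>= 2, <= number of distinct descriptors).
#' @param n_sample Maximum descriptors used for clustering (default 100000).
#' @param seed Integer seed driving both sampling and initialization.
#' @param max_iter,tol Lloyd iteration cap and center-shift tolerance.
#' @return Object of class `codebook`: list with `words` (M x d matrix), `M`,
#'   `train_seed`, `n_sampled`.
#' @export
build_dictionary <- function(descriptor_pool, M, n_sample = 100000, seed = 1,
                             max_iter = 100, tol = 1e-8) {
  if (!is.matrix(descriptor_pool) || nrow(descriptor_pool) == 0) {
    stop_fmt("descriptor pool must be a nonempty matrix")
  }
  M <- as.integer(M)
  if (M < 2) stop_fmt("codebook size M must be >= 2")
  n_distinct <- nrow(unique(descriptor_pool))
  if (M > n_distinct) {
    stop_fmt("codebook size M = %d exceeds the %d distinct descriptors available",
             M, n_distinct)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(descriptor_pool)
  take <- min(n_sample, n)
  X <- descriptor_pool[sample.int(n, take), , drop = FALSE]
  W <- kmeanspp_init(X, M)
  for (it in seq_len(max_iter)) {
    D <- sqdist(X, W)
    assign <- max.col(-D, ties.method = "first")
    Wnew <- W
    counts <- tabulate(assign, nbins = M)
    for (m in which(counts > 0)) {
      Wnew[m, ] <- colMeans(X[assign == m, , drop = FALSE])
    }
    empty <- which(counts == 0)
    if (length(empty) > 0) {
      # re-seed empty clusters from the points farthest from their centers
      dmin <- D[cbind(seq_len(nrow(X)), assign)]
      far <- order(dmin, decreasing = TRUE)[seq_along(empty)]
      Wnew[empty, ] <- X[far, , drop = FALSE]
    }
    shift <- max(rowSums((Wnew - W)^2))
    W <- Wnew
    if (shift < tol && length(empty) == 0) break
  }
  structure(list(words = W, M = M, train_seed = seed, n_sampled = take),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("Visual codebook: %d words of dimension %d (trained on %d descriptors, seed %d)\n",
              x$M, ncol(x$words), x$n_sampled, x$train_seed))
  invisible(x)
}

#' Serialize a codebook with its provenance
#'
#' @param codebook A `codebook`.
#' @param path Output CSV path for the words; a JSON sidecar at `<path>.json`
#'   records M, p implied dimension, seed and sample count.
#' @return Invisibly, the sidecar path.
#' @export
write_codebook <- function(codebook, path) {
  utils::write.csv(as.data.frame(codebook$words), path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(M = codebook$M, dim = ncol(codebook$words),
                            train_seed = codebook$train_seed,
                            n_sampled = codebook$n_sampled),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Vector quantization coding
#'
#' Hard assignment: each descriptor becomes a one-hot code at its nearest
#' codebook word (Euclidean), ties broken toward the lowest word index.
#'
#' @param descriptors Numeric vector (one descriptor) or N x d matrix.
#' @param codebook A `codebook`.
#' @return N x M matrix of codes (a 1 x M matrix for a single descriptor).
#' @export
encode_vq <- function(descriptors, codebook) {
  X <- if (is.matrix(descriptors)) descriptors else matrix(descriptors, 1)
  if (ncol(X) != ncol(codebook$words)) {
    stop_fmt("descriptor dimension %d does not match codebook dimension %d",
             ncol(X), ncol(codebook$words))
  }
  D <- sqdist(X, codebook$words)
  nearest <- max.col(-D, ties.method = "first")
  C <- matrix(0, nrow(X), codebook$M)
  C[cbind(seq_len(nrow(X)), nearest)] <- 1
  C
}

#' Localized soft-assignment coding (SA-k)
#'
#' Gaussian-weighted assignment over the `k_nn` nearest codebook words:
#' weights proportional to exp(-||x - w||^2 / (2 sigma^2)) over those words,
#' normalized to sum 1, zero elsewhere. With the `"beta"` convention the
#' bandwidth is read as exp(-sigma * ||x - w||^2) instead.
#'
#' @inheritParams encode_vq
#' @param k_nn Number of nearest words used (1 <= k_nn <= M); `k_nn = 1`
#'   reduces to vector quantization.
#' @param sigma Gaussian kernel bandwidth (default 0.5).
#' @param convention `"sigma"` (default) or `"beta"`.
#' @return N x M matrix of codes.
#' @export
encode_sa_k <- function(descriptors, codebook, k_nn, sigma = 0.5,
                        convention = c("sigma", "beta")) {
  convention <- match.arg(convention)
  X <- if (is.matrix(descriptors)) descriptors else matrix(descriptors, 1)
  M <- codebook$M
  if (k_nn < 1 || k_nn > M) stop_fmt("k_nn must be in 1..M")
  D <- sqdist(X, codebook$words)
  C <- matrix(0, nrow(X), M)
  for (i in seq_len(nrow(X))) {
    nn <- order(D[i, ])[seq_len(k_nn)]
    w <- if (convention == "sigma") exp(-D[i, nn] / (2 * sigma^2))
         else exp(-sigma * D[i, nn])
    if (sum(w) == 0) w <- rep(1, k_nn)  # numerically underflowed: uniform over the k nearest
    C[i, nn] <- w / sum(w)
  }
  C
}

#' Pool codes over a region
#'
#' Elementwise sum or max of the code vectors of a region's descriptors.
#' An empty code set yields the zero vector.
#'
#' @param codes N x M matrix of codes (rows may be zero for none).
#' @param method `"sum"` or `"max"`.
#' @param M Codebook size, required when `codes` has zero rows.
#' @return Numeric vector of length M.
#' @export
pool_codes <- function(codes, method = c("sum", "max"), M = NULL) {
  method <- match.arg(method)
  if (is.null(codes) || nrow(codes) == 0) {
    if (is.null(M)) stop_fmt("M must be given to pool an empty code set")
    return(numeric(M))
  }
  if (method == "sum") colSums(codes) else apply(codes, 2, max)
}
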