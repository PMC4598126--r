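# Independent brute-force oracles, deliberately naive so they share no code
# path with the implementation they check.

# Dilation as the union of translated disks.
brute_dilate <- function(mask, R) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  offs <- expand.grid(dy = -R:R, dx = -R:R)
  offs <- offs[offs$dy^2 + offs$dx^2 <= R^2, ]
  for (p in which(mask)) {
    y <- (p - 1) %% nr + 1; x <- (p - 1) %/% nr + 1
    ys <- y + offs$dy; xs <- x + offs$dx
    ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    out[cbind(ys[ok], xs[ok])] <- TRUE
  }
  out
}

# Distance to nearest background pixel, exhaustive min; the image is
# surrounded by background, whose nearest representatives lie in a 1-pixel
# pad ring.
brute_border_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- which(!padded, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (p in which(mask)) {
    y <- (p - 1) %% nr + 2; x <- (p - 1) %/% nr + 2
    out[y - 1, x - 1] <- sqrt(min((bg[, 1] - y)^2 + (bg[, 2] - x)^2))
  }
  out
}

# Exhaustive symmetric pair scan for the isotropic GLCM.
brute_glcm_isotropic <- function(levels, region, G, D) {
  nr <- nrow(levels); nc <- ncol(levels)
  offs <- list(c(0, D), c(-D, D), c(-D, 0), c(-D, -D))
  total <- matrix(0, G, G)
  for (off in offs) {
    C <- matrix(0, G, G)
    for (y in 1:nr) for (x in 1:nc) {
      y2 <- y + off[1]; x2 <- x + off[2]
      if (y2 < 1 || y2 > nr || x2 < 1 || x2 > nc) next
      if (region[y, x] && region[y2, x2]) {
        i <- levels[y, x] + 1; j <- levels[y2, x2] + 1
        C[i, j] <- C[i, j] + 1
        C[j, i] <- C[j, i] + 1
      }
    }
    total <- total + C
  }
  P <- total / 4
  if (sum(P) == 0) P else P / sum(P)
}

# 4-connected component count by flood fill.
n_components_4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0) next
    comp <- comp + 1L
    queue <- start
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      if (lab[p] != 0) next
      lab[p] <- comp
      y <- (p - 1) %% nrow(mask) + 1; x <- (p - 1) %/% nrow(mask) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        y2 <- y + d[1]; x2 <- x + d[2]
        if (y2 >= 1 && y2 <= nrow(mask) && x2 >= 1 && x2 <= ncol(mask) &&
            mask[y2, x2] && lab[y2, x2] == 0) {
          queue <- c(queue, (x2 - 1) * nrow(mask) + y2)
        }
      }
    }
  }
  comp
}

# Random blob-ish mask that never touches the border (for partition tests).
# The polar perturbation can push the realized radius up to ~1.45x the
# nominal one, so placement leaves that much clearance.
random_mask <- function(size = 24, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- runif(1, 3, (size / 2 - 3) / 1.45)
  lo <- 1.45 * r + 2
  ringspm::generate_tumor_mask(size, c(runif(1, lo, size - lo),
                                       runif(1, lo, size - lo)),
                               r, irregularity = runif(1, 0, 0.4))
}

# Small phantom dataset shared across tests (built once per test run).
tiny_phantom <- local({
  cache <- new.env()
  function(scenario = "texture_only", n_patients = 9, slices = 2, size = 48,
           noise_sd = 0.02, seed = 42) {
    key <- paste(scenario, n_patients, slices, size, noise_sd, seed)
    if (is.null(cache[[key]])) {
      cfg <- ringspm::phantom_config(
        n_patients = n_patients, slices_per_patient = slices,
        image_size = size, classes = ringspm::phantom_classes(scenario),
        tumor_radius_range = c(7, 10), margin = 8, noise_sd = noise_sd,
        seed = seed)
      cache[[key]] <- ringspm::generate_phantom_dataset(
        cfg, file.path(tempdir(), paste0("phantom_", abs(sum(utf8ToInt(key))))))
    }
    cache[[key]]
  }
})

# Fast config for classifier-bearing tests: a single C skips the inner grid
# search, keeping runtimes small where C selection is not the property under
# test.
fast_config <- function(...) {
  ringspm::ringspm_config(C_grid = 10, ...)
}
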