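# Synthetic phantom datasets with the statistical structure the method
# exploits: class signal can be placed in the tumor texture, in a
# peritumoral annulus, or in the radial intensity layout, independently.

#' Built-in phantom class specifications
#'
#' Returns three class parameter sets placing the discriminative signal in a
#' chosen channel:
#' \describe{
#'   \item{full}{signal in all three channels (texture, context, radial).}
#'   \item{texture_only}{only the tumor-interior mean differs; the
#'     peritumoral annulus and radial layout are identical across classes —
#'     the calibration dataset for the R = 0 baseline.}
#'   \item{context_only}{only the peritumoral annulus intensity differs;
#'     with R = 0 nothing separates the classes, with R at least the annulus
#'     width the context enters the ROI.}
#'   \item{radial_only}{only the radial intensity layout differs. All three
#'     profiles are two-valued step functions of the area-quantile of border
#'     distance with exactly equal 50/50 intensity mass, so whole-ROI
#'     histograms are class-identical and only ring partition (L >= 1) can
#'     separate them.}
#'   \item{null}{all classes identical; any pipeline performs at chance.}
#' }
#'
#' @param scenario One of `"full"`, `"texture_only"`, `"context_only"`,
#'   `"radial_only"`, `"null"`.
#' @return List of 3 class spec lists.
#' @export
phantom_classes <- function(scenario = c("full", "texture_only", "context_only",
                                         "radial_only", "null")) {
  scenario <- match.arg(scenario)
  # All class structures keep their intensities strictly inside the
  # background's percentile window: the background spans a wide intensity
  # range (like CSF-to-fat in real brain MRI), so the slice-level 1st/99th
  # percentile anchors are pinned by class-independent background tails and
  # the min-max normalization cannot leak class information.
  base <- list(tumor_mean = 0.55, tumor_sd = 0.03, tumor_corlen = 1.5,
               context_offset = 0, context_sd = 0.03, context_corlen = 1.5,
               radial_shape = "none", radial_amplitude = 0)
  mk <- function(name, ...) {
    spec <- utils::modifyList(base, list(...))
    c(list(name = name), spec)
  }
  switch(scenario,
    full = list(
      mk("meningioma", tumor_mean = 0.40, context_offset = -0.10,
         radial_shape = "up", radial_amplitude = 0.05),
      mk("glioma", tumor_mean = 0.55, context_offset = 0,
         radial_shape = "down", radial_amplitude = 0.05),
      mk("pituitary", tumor_mean = 0.70, context_offset = 0.10,
         radial_shape = "bump", radial_amplitude = 0.05)),
    texture_only = list(
      mk("meningioma", tumor_mean = 0.30),
      mk("glioma", tumor_mean = 0.50),
      mk("pituitary", tumor_mean = 0.70)),
    context_only = list(
      mk("meningioma", context_offset = -0.20),
      mk("glioma", context_offset = 0),
      mk("pituitary", context_offset = 0.20)),
    radial_only = list(
      mk("meningioma", radial_shape = "up", radial_amplitude = 0.12),
      mk("glioma", radial_shape = "down", radial_amplitude = 0.12),
      mk("pituitary", radial_shape = "bump", radial_amplitude = 0.12)),
    null = list(mk("meningioma"), mk("glioma"), mk("pituitary"))
  )
}

#' Phantom dataset configuration
#'
#' @param n_patients Number of patients (>= number of classes).
#' @param slices_per_patient Slices generated per patient.
#' @param image_size Image side length in pixels.
#' @param classes Class specification list (see [phantom_classes()]).
#' @param tumor_radius_range Min/max nominal tumor radius in pixels.
#' @param shape_irregularity Amplitude of the radial boundary perturbation
#'   in \[0, 0.5\].
#' @param annulus_width Width in pixels of the peritumoral context annulus.
#' @param margin Minimum clearance between the tumor and the image border;
#'   must be at least the largest dilation radius the dataset will be
#'   analysed with, so dilated ROIs are never clipped.
#' @param background_mean Background intensity (normalized units).
#' @param background_sd Background texture amplitude. A wide background
#'   spread keeps the slice-level percentile anchors pinned by the
#'   background's tails rather than by any class-dependent structure.
#' @param noise_sd Additive Gaussian noise scale (>= 0).
#' @param seed Integer master seed; all randomness flows from it through
#'   per-slice substreams.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 15, slices_per_patient = 4,
                           image_size = 64, classes = phantom_classes("full"),
                           tumor_radius_range = c(8, 13),
                           shape_irregularity = 0.25, annulus_width = 6,
                           margin = 10, background_mean = 0.5,
                           background_sd = 0.15, noise_sd = 0.02, seed = 1) {
  if (n_patients < length(classes)) {
    stop_fmt("n_patients (%d) must be >= number of classes (%d)",
             n_patients, length(classes))
  }
  if (noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  if (shape_irregularity < 0 || shape_irregularity > 0.5) {
    stop_fmt("shape_irregularity must be in [0, 0.5]")
  }
  rmax <- max(tumor_radius_range) * (1 + shape_irregularity)
  if (2 * (rmax + margin) + 2 >= image_size) {
    stop_fmt("image_size %d too small for tumor radius %g plus margin %d",
             image_size, max(tumor_radius_range), margin)
  }
  structure(list(n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 image_size = as.integer(image_size), classes = classes,
                 tumor_radius_range = tumor_radius_range,
                 shape_irregularity = shape_irregularity,
                 annulus_width = as.integer(annulus_width),
                 margin = as.integer(margin),
                 background_mean = background_mean,
                 background_sd = background_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Gaussian smoothing by explicit separable kernel matrices (exact, no FFT;
# rows renormalized so edges keep unit mass).
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  n <- nrow(mat); m <- ncol(mat)
  smat <- function(k) {
    S <- exp(-outer(seq_len(k), seq_len(k), "-")^2 / (2 * sigma^2))
    S / rowSums(S)
  }
  smat(n) %*% mat %*% t(smat(m))
}

# Smoothed, standardized noise field: mean 0, sd 1 (given nonzero variance).
texture_field <- function(n, m, corlen) {
  z <- matrix(stats::rnorm(n * m), n, m)
  z <- gaussian_smooth(z, corlen)
  s <- stats::sd(z)
  if (s > 0) (z - mean(z)) / s else z * 0
}

#' Generate a star-convex tumor mask
#'
#' A discrete disk whose polar radius is perturbed by low-order Fourier
#' harmonics (orders 2..4) with total amplitude `irregularity`, then rescaled
#' so the enclosed area stays close to the unperturbed disk's. Star-convexity
#' about the center keeps the border distance transform well behaved.
#' `irregularity = 0` yields the exact discrete disk
#' \{(x, y) : (x - cx)^2 + (y - cy)^2 <= r^2\}.
#'
#' @param image_size Side length of the square image.
#' @param center Numeric length-2 (row, col) center.
#' @param radius Nominal radius in pixels (>= 2).
#' @param irregularity Perturbation amplitude in \[0, 0.5\].
#' @param seed Optional integer seed for the harmonic draw.
#' @return Logical mask matrix; errors if the mask touches the image border.
#' @export
generate_tumor_mask <- function(image_size, center, radius, irregularity = 0,
                                seed = NULL) {
  if (radius < 2) stop_fmt("tumor radius must be >= 2")
  if (irregularity < 0 || irregularity > 0.5) {
    stop_fmt("irregularity must be in [0, 0.5]")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rows <- matrix(seq_len(image_size), image_size, image_size)
  cols <- t(rows)
  dy <- rows - center[1]; dx <- cols - center[2]
  if (irregularity == 0) {
    mask <- dy^2 + dx^2 <= radius^2
  } else {
    h <- 2:4
    amp <- stats::runif(length(h))
    amp <- amp / sum(amp) * irregularity
    phase <- stats::runif(length(h), 0, 2 * pi)
    pert <- function(theta) {
      out <- rep(1, length(theta))
      for (i in seq_along(h)) out <- out + amp[i] * cos(h[i] * theta + phase[i])
      out
    }
    # rescale so mean(r(theta)^2) = radius^2, keeping the area near pi r^2
    grid <- seq(0, 2 * pi, length.out = 720)
    scale <- sqrt(mean(pert(grid)^2))
    theta <- atan2(dy, dx)
    r <- radius * pert(theta) / scale
    mask <- dy^2 + dx^2 <= r^2
  }
  if (any(mask[1, ]) || any(mask[image_size, ]) ||
      any(mask[, 1]) || any(mask[, image_size])) {
    stop_fmt("tumor mask touches the image border (center %g,%g radius %g)",
             center[1], center[2], radius)
  }
  mask
}

# Two-valued radial step profiles of the area-quantile q of border distance.
# All three have exactly 50% mass at +A and 50% at -A, so whole-ROI
# histograms are identical across them.
radial_profile <- function(shape, q, amplitude) {
  switch(shape,
    none = numeric(length(q)),
    up   = ifelse(q > 0.5, amplitude, -amplitude),
    down = ifelse(q > 0.5, -amplitude, amplitude),
    bump = ifelse(q > 0.25 & q <= 0.75, amplitude, -amplitude),
    stop_fmt("unknown radial profile shape '%s'", shape))
}

render_phantom_slice <- function(config, class_spec, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  S <- config$image_size
  radius <- stats::runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
  lo <- ceiling(radius * (1 + config$shape_irregularity)) + config$margin + 1
  hi <- S - lo + 1
  mask <- NULL
  for (attempt in 1:20) {
    center <- c(stats::runif(1, lo, hi), stats::runif(1, lo, hi))
    mask <- tryCatch(generate_tumor_mask(S, center, radius,
                                         config$shape_irregularity),
                     error = function(e) NULL)
    if (!is.null(mask)) break
  }
  if (is.null(mask)) stop_fmt("tumor placement failed after bounded retries")

  img <- config$background_mean + config$background_sd * texture_field(S, S, 2)
  annulus <- augment_roi(mask, config$annulus_width) & !mask
  ctx <- config$background_mean + class_spec$context_offset +
    class_spec$context_sd * texture_field(S, S, class_spec$context_corlen)
  img[annulus] <- ctx[annulus]
  tum <- class_spec$tumor_mean +
    class_spec$tumor_sd * texture_field(S, S, class_spec$tumor_corlen)
  img[mask] <- tum[mask]
  if (class_spec$radial_shape != "none") {
    d <- border_distance(mask)[mask]
    q <- rank(d, ties.method = "average") / length(d)
    img[mask] <- img[mask] +
      radial_profile(class_spec$radial_shape, q, class_spec$radial_amplitude)
  }
  if (config$noise_sd > 0) img <- img + config$noise_sd * stats::rnorm(length(img))
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(S, S)
  list(levels = round(img * 4095), mask = mask)
}

#' Generate a phantom dataset on disk
#'
#' Writes one 16-bit TIFF image and one 0/255 PNG mask per slice plus a
#' `manifest.csv`, in the layout [load_manifest()] reads. Patients are
#' assigned to classes round-robin (per-class counts differ by at most one);
#' each patient carries exactly one class. All randomness flows from
#' `config$seed` through per-slice substreams, so the same configuration
#' reproduces byte-identical files.
#'
#' @param config A `phantom_config`.
#' @param out_dir Output directory (created if needed).
#' @return The `slice_manifest` of the written dataset.
#' @export
generate_phantom_dataset <- function(config, out_dir) {
  if (!inherits(config, "phantom_config")) stop_fmt("config must be a phantom_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pi in seq_len(config$n_patients)) {
    class_spec <- config$classes[[((pi - 1) %% length(config$classes)) + 1]]
    patient_id <- sprintf("P%03d", pi)
    for (si in seq_len(config$slices_per_patient)) {
      stream <- (pi - 1) * config$slices_per_patient + si
      sl <- render_phantom_slice(config, class_spec,
                                 child_seed(config$seed, stream))
      stem <- sprintf("p%03d_s%02d", pi, si)
      tiff::writeTIFF(sl$levels / 65535, file.path(out_dir, paste0(stem, ".tif")),
                      bits.per.sample = 16, compression = "none")
      png::writePNG(matrix(as.numeric(sl$mask), nrow(sl$mask)),
                    file.path(out_dir, paste0(stem, "_mask.png")))
      rows[[length(rows) + 1]] <- data.frame(
        image_path = paste0(stem, ".tif"),
        mask_path = paste0(stem, "_mask.png"),
        patient_id = patient_id, label = class_spec$name,
        stringsAsFactors = FALSE)
    }
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE,
                   quote = FALSE)
  load_manifest(manifest_path)
}
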