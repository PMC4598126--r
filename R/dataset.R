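#' Load a dataset manifest
#'
#' Reads a CSV manifest with header columns `image_path`, `mask_path`,
#' `patient_id`, `label` (one row per slice). Relative paths are resolved
#' against the manifest's directory. The class set is the sorted set of
#' distinct labels; internal integer class codes always follow this sorted
#' order so label/index correspondence is stable across folds.
#'
#' @param path Path to the manifest CSV.
#' @return An object of class `slice_manifest`: a list with `records`
#'   (data.frame with columns image_path, mask_path, patient_id, label,
#'   slice_id), `classes` (sorted character vector) and `root` (directory
#'   paths were resolved against).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop_fmt("manifest file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("image_path", "mask_path", "patient_id", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_fmt("manifest is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop_fmt("manifest %s contains no records", path)
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  records <- data.frame(
    image_path = resolve(df$image_path),
    mask_path  = resolve(df$mask_path),
    patient_id = df$patient_id,
    label      = df$label,
    slice_id   = tools::file_path_sans_ext(basename(df$image_path)),
    stringsAsFactors = FALSE
  )
  key <- paste(records$patient_id, records$slice_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_fmt("duplicate (patient_id, slice_id) record in manifest: %s",
             gsub("\r", " / ", dup))
  }
  for (p in c(records$image_path, records$mask_path)) {
    if (!file.exists(p)) stop_fmt("manifest references missing file: %s", p)
  }
  structure(list(records = records,
                 classes = sort(unique(records$label)),
                 root = root),
            class = "slice_manifest")
}

#' @export
print.slice_manifest <- function(x, ...) {
  cat("Slice manifest:", nrow(x$records), "slices,",
      length(unique(x$records$patient_id)), "patients,",
      length(x$classes), "classes (", paste(x$classes, collapse = ", "), ")\n")
  invisible(x)
}

read_png_levels <- function(path) {
  # png::readPNG rescales to [0,1]; recover the integer code using the bit
  # depth recorded in the IHDR chunk (byte 25 of the file).
  bits <- as.integer(readBin(path, "raw", n = 25L)[25L])
  if (!bits %in% c(1L, 2L, 4L, 8L, 16L)) bits <- 8L
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  round(v * (2^bits - 1))
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    read_png_levels(path)
  } else if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    v
  } else {
    stop_fmt("unsupported image format '%s' (expected PNG or TIFF): %s", ext, path)
  }
}

#' Load one annotated slice
#'
#' Reads the image and mask files of a manifest record. Intensities are
#' preserved as stored (integer gray codes for 8/16-bit PNG/TIFF); the mask
#' is binarized at > 0 so both 0/1 and 0/255 mask dialects are accepted.
#'
#' @param record A single row of `manifest$records` (data.frame or list with
#'   image_path, mask_path, patient_id, label, slice_id).
#' @return An object of class `annotated_slice`: list with `image` (numeric
#'   matrix), `mask` (logical matrix), `label`, `patient_id`, `slice_id`.
#' @export
load_slice <- function(record) {
  img <- read_image_file(record$image_path)
  msk <- read_png_levels(record$mask_path)
  if (!identical(dim(img), dim(msk))) {
    stop_fmt("image/mask shape mismatch for slice %s: image %s vs mask %s",
             record$slice_id,
             paste(dim(img), collapse = "x"), paste(dim(msk), collapse = "x"))
  }
  mask <- msk > 0
  if (!any(mask)) stop_fmt("mask for slice %s has no foreground pixels", record$slice_id)
  structure(list(image = img, mask = mask,
                 label = record$label,
                 patient_id = record$patient_id,
                 slice_id = record$slice_id),
            class = "annotated_slice")
}

#' @export
print.annotated_slice <- function(x, ...) {
  cat(sprintf("Annotated slice %s (patient %s, label %s): %dx%d image, %d ROI pixels\n",
              x$slice_id, x$patient_id, x$label,
              nrow(x$image), ncol(x$image), sum(x$mask)))
  invisible(x)
}

#' Serialize a feature matrix with its provenance
#'
#' Writes the matrix as CSV next to a JSON sidecar recording the full
#' parameter set that produced it, so any feature file can be traced back to
#' its configuration.
#'
#' @param X Numeric matrix (rows = slices).
#' @param path Output CSV path; the sidecar is written at `<path>.json`.
#' @param config The `ringspm_config` that produced the features.
#' @param row_ids Optional row identifiers (e.g. slice ids).
#' @return Invisibly, the sidecar path.
#' @export
write_feature_matrix <- function(X, path, config, row_ids = rownames(X)) {
  df <- as.data.frame(X)
  if (!is.null(row_ids)) df <- cbind(slice_id = row_ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(parameters = unclass(config),
                            n_rows = nrow(X), n_cols = ncol(X)),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
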