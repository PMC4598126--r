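# Patient-stratified cross-validation and report metrics.

#' Patient-to-class map from slice-level labels
#'
#' Condenses slice labels to one class per patient. A patient whose slices
#' carry conflicting labels is assigned the majority slice label with a
#' warning (ties toward the alphabetically first label).
#'
#' @param patients Patient id per slice.
#' @param labels Class label per slice.
#' @return Named character vector: patient id -> class.
#' @export
patient_class_map <- function(patients, labels) {
  patients <- as.character(patients); labels <- as.character(labels)
  out <- character(0)
  for (p in unique(patients)) {
    tab <- sort(table(labels[patients == p]), decreasing = TRUE)
    if (length(tab) > 1) {
      warn_fmt("patient %s has slices of %d classes; assigned majority label '%s'",
               p, length(tab), names(tab)[1])
    }
    out[p] <- names(tab)[1]
  }
  out
}

#' Patient-stratified fold assignment
#'
#' Partitions patients into `n_folds` folds so that the per-class patient
#' counts per fold differ by at most one: within each class, patients are
#' shuffled by the seed and dealt round-robin, with the starting fold rotated
#' between classes so overall fold sizes also stay within one of each other.
#' Grouping by patient guarantees no patient's slices ever straddle the
#' train/test divide.
#'
#' @param patient_labels Named vector: patient id -> class (see
#'   [patient_class_map()]).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the shuffles.
#' @return Object of class `fold_assignment`: list with `assignment` (named
#'   integer vector patient -> fold in 0..n_folds-1) and `n_folds`.
#' @export
patient_stratified_folds <- function(patient_labels, n_folds = 5, seed = 1) {
  if (length(patient_labels) == 0) stop_fmt("no patients to assign")
  n_folds <- as.integer(n_folds)
  classes <- sort(unique(patient_labels))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  assignment <- integer(0)
  start <- 0L
  for (cl in classes) {
    ids <- names(patient_labels)[patient_labels == cl]
    if (length(ids) < n_folds) {
      warn_fmt("class '%s' has only %d patients for %d folds; some folds lack this class",
               cl, length(ids), n_folds)
    }
    ids <- sample(ids)
    f <- (start + seq_along(ids) - 1L) %% n_folds
    assignment[ids] <- f
    start <- (start + length(ids)) %% n_folds
  }
  structure(list(assignment = assignment, n_folds = n_folds),
            class = "fold_assignment")
}

#' Per-class sensitivity and specificity from a confusion matrix
#'
#' Rows are true classes, columns predicted. Sensitivity of class c is
#' cm\[c,c\] / rowSums(cm)\[c\]; specificity is one-vs-rest, 1 minus the
#' false-positive count in column c divided by the total number of
#' non-class-c slices. Values are returned as percentages rounded to one
#' decimal. A class with no true slices gets NaN sensitivity with a warning.
#'
#' @param cm Square numeric confusion matrix (true rows x predicted columns).
#' @return List with `sensitivity` and `specificity` (named percent vectors)
#'   and `accuracy` (overall percent, trace / total).
#' @export
sensitivity_specificity <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_fmt("confusion matrix must be square")
  if (any(cm < 0)) stop_fmt("confusion matrix entries must be nonnegative")
  n <- nrow(cm)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- as.character(seq_len(n))
  sens <- spec <- stats::setNames(numeric(n), cls)
  for (c in seq_len(n)) {
    pos <- sum(cm[c, ])
    if (pos == 0) {
      warn_fmt("class %s has no true slices; sensitivity undefined", cls[c])
      sens[c] <- NaN
    } else {
      sens[c] <- 100 * cm[c, c] / pos
    }
    neg <- sum(cm[-c, ])
    fp <- sum(cm[-c, c])
    spec[c] <- if (neg == 0) NaN else 100 * (1 - fp / neg)
  }
  list(sensitivity = round(sens, 1), specificity = round(spec, 1),
       accuracy = round(100 * sum(diag(cm)) / sum(cm), 1))
}

#' Patient-stratified cross-validation of the full pipeline
#'
#' Runs `n_folds`-fold cross-validation at the slice level with folds drawn
#' over patients: for each fold, all fold-dependent state (codebook, SVM
#' penalty, classifier) is fitted on the training slices only, then the
#' held-out slices are predicted. Reports per-fold and pooled confusion
#' matrices, per-class sensitivity/specificity from the pooled matrix, and
#' both the mean of per-fold accuracies and the pooled accuracy.
#'
#' @param manifest A `slice_manifest` (or path to a manifest CSV).
#' @param config A `ringspm_config`.
#' @param seed Seed for fold assignment and fold-level substreams; defaults
#'   to `config$seed`.
#' @param folds Optional precomputed `fold_assignment`, so paired
#'   comparisons across configurations can reuse identical folds.
#' @return Object of class `ringspm_cv` with fields `per_fold_cm`,
#'   `pooled_cm`, `fold_accuracies`, `mean_accuracy`, `pooled_accuracy`,
#'   `sensitivity`, `specificity`, `folds`, `config`.
#' @export
cross_validate <- function(manifest, config, seed = config$seed, folds = NULL) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  rec <- manifest$records
  slices <- lapply(seq_len(nrow(rec)), function(i) load_slice(rec[i, ]))
  if (is.null(folds)) {
    pl <- patient_class_map(rec$patient_id, rec$label)
    folds <- patient_stratified_folds(pl, n_folds = config$n_folds, seed = seed)
  }
  fold_of <- folds$assignment[rec$patient_id]
  classes <- manifest$classes
  per_fold_cm <- list()
  fold_acc <- numeric(0)
  for (f in sort(unique(fold_of))) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    fit <- ringspm(manifest, config, subset = train, slices = slices,
                   seed = child_seed(seed, f))
    pred <- predict(fit, slices[test])
    truth <- factor(rec$label[test], levels = classes)
    cm <- table(truth, factor(pred, levels = classes))
    cm <- unclass(as.matrix(cm))
    dimnames(cm) <- list(classes, classes)
    per_fold_cm[[length(per_fold_cm) + 1]] <- cm
    fold_acc <- c(fold_acc, sum(diag(cm)) / sum(cm))
  }
  pooled <- Reduce(`+`, per_fold_cm)
  ss <- suppressWarnings(sensitivity_specificity(pooled))
  structure(list(per_fold_cm = per_fold_cm, pooled_cm = pooled,
                 fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 pooled_accuracy = sum(diag(pooled)) / sum(pooled),
                 sensitivity = ss$sensitivity, specificity = ss$specificity,
                 folds = folds, config = config, classes = classes),
            class = "ringspm_cv")
}

#' @export
print.ringspm_cv <- function(x, ...) {
  cat(sprintf("%d-fold patient-stratified cross-validation (%s, R=%d, L=%d, %s)\n",
              length(x$per_fold_cm), x$config$feature, x$config$R, x$config$L,
              x$config$mode))
  cat(sprintf("  mean fold accuracy: %.2f%%   pooled accuracy: %.2f%%\n",
              100 * x$mean_accuracy, 100 * x$pooled_accuracy))
  invisible(x)
}

#' @export
summary.ringspm_cv <- function(object, ...) {
  print(object)
  cat("Pooled confusion matrix (true rows x predicted columns):\n")
  print(object$pooled_cm)
  cat("Per-class sensitivity (%):\n"); print(object$sensitivity)
  cat("Per-class specificity (%):\n"); print(object$specificity)
  cat(sprintf("Per-fold accuracies: %s\n",
              paste(sprintf("%.1f%%", 100 * object$fold_accuracies), collapse = ", ")))
  invisible(object)
}

#' Write a cross-validation report to disk
#'
#' Emits the report as machine-readable JSON and a human-readable Markdown
#' table, with the resolved configuration and seed for reproducibility.
#'
#' @param report A `ringspm_cv`.
#' @param path Output path stem; writes `<path>.json` and `<path>.md`.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  js <- list(config = unclass(report$config),
             classes = report$classes,
             pooled_confusion = report$pooled_cm,
             fold_accuracies = report$fold_accuracies,
             mean_accuracy = report$mean_accuracy,
             pooled_accuracy = report$pooled_accuracy,
             sensitivity = as.list(report$sensitivity),
             specificity = as.list(report$specificity),
             package_version = as.character(utils::packageVersion("ringspm")))
  jsonlite::write_json(js, paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  md <- c(sprintf("# Cross-validation report (%s)", report$config$feature),
          "",
          sprintf("- mean fold accuracy: %.2f%%", 100 * report$mean_accuracy),
          sprintf("- pooled accuracy: %.2f%%", 100 * report$pooled_accuracy),
          "",
          paste("| true\\pred |", paste(report$classes, collapse = " | "), "|"),
          paste(c("|---", rep("|---", length(report$classes)), "|"), collapse = ""),
          vapply(seq_along(report$classes), function(i) {
            paste("|", report$classes[i], "|",
                  paste(report$pooled_cm[i, ], collapse = " | "), "|")
          }, character(1)))
  writeLines(md, paste0(path, ".md"))
  invisible(paste0(path, ".json"))
}

#' Regularized LDA projection to 2D
#'
#' Projects descriptors on the top-2 eigenvectors of (Sw + lambda I)^-1 Sb,
#' where Sw and Sb are the within- and between-class scatter matrices and
#' lambda a small ridge constant guarding against singular Sw. The basis sign
#' convention makes each eigenvector's first nonzero entry positive.
#'
#' @param X n x d descriptor matrix.
#' @param y Class labels.
#' @param lam Ridge constant; default `1e-3 * trace(Sw) / d`.
#' @return List with `coords` (n x 2), `basis` (d x 2), `eigenvalues`.
#' @export
lda_project_2d <- function(X, y, lam = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop_fmt("LDA needs at least 2 classes")
  if (nrow(X) < 3) stop_fmt("LDA needs at least 3 samples")
  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    Xcc <- sweep(Xc, 2, mc)
    Sw <- Sw + crossprod(Xcc)
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  if (is.null(lam)) lam <- 1e-3 * sum(diag(Sw)) / d
  if (lam <= 0) stop_fmt("ridge constant lam must be > 0")
  Mt <- solve(Sw + lam * diag(d), Sb)
  eig <- eigen(Mt)
  ord <- order(Re(eig$values), decreasing = TRUE)[1:2]
  basis <- Re(eig$vectors[, ord, drop = FALSE])
  for (j in 1:2) {
    nz <- which(abs(basis[, j]) > 1e-12)[1]
    if (!is.na(nz) && basis[nz, j] < 0) basis[, j] <- -basis[, j]
  }
  list(coords = X %*% basis, basis = basis,
       eigenvalues = Re(eig$values[ord]))
}
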