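# Classifiers over region descriptors: one-vs-one SVM on the histogram
# intersection kernel, sparse-representation classification via OMP, and kNN.

#' Histogram intersection kernel
#'
#' K(x, y) = sum_i min(x_i, y_i), a Mercer kernel on nonnegative vectors.
#'
#' @param x,y Nonnegative numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
hik <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("hik(): vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop_fmt("hik() requires nonnegative vectors")
  sum(pmin(x, y))
}

#' Histogram intersection Gram matrix
#'
#' @param X n x d matrix of nonnegative descriptors (rows).
#' @param Y Optional m x d matrix; defaults to `X`.
#' @return n x m kernel matrix.
#' @export
hik_gram <- function(X, Y = X) {
  if (any(X < 0) || any(Y < 0)) stop_fmt("hik_gram() requires nonnegative entries")
  K <- matrix(0, nrow(X), nrow(Y))
  for (j in seq_len(nrow(Y))) {
    K[, j] <- colSums(pmin(t(X), Y[j, ]))
  }
  K
}

# Train one binary C-SVC on a precomputed kernel submatrix; returns the
# pieces needed to evaluate its decision function on new kernel columns.
fit_binary_svm <- function(K, y01, C) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(y01), type = "C-svc",
                     C = C, scaled = FALSE)
  sv <- kernlab::SVindex(m)
  # orient the decision value so positive means the SECOND factor level
  dtr <- kernlab::predict(m, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]),
                          type = "decision")[, 1]
  lev <- levels(factor(y01))
  mu1 <- mean(dtr[y01 == lev[2]]); mu0 <- mean(dtr[y01 == lev[1]])
  flip <- if (mu1 >= mu0) 1 else -1
  list(model = m, sv = sv, flip = flip, levels = lev)
}

binary_decision <- function(fit, Knew_sv) {
  d <- kernlab::predict(fit$model, kernlab::as.kernelMatrix(Knew_sv),
                        type = "decision")[, 1]
  d * fit$flip
}

#' Train a one-vs-one HIK-SVM
#'
#' Selects the SVM penalty C from `C_grid` by patient-grouped inner
#' cross-validation on the training set (highest mean accuracy; ties go to
#' the smallest C), then trains one binary HIK-kernel SVM per class pair on
#' the full training set using the precomputed Gram matrix.
#'
#' @param X n x d matrix of nonnegative descriptors.
#' @param y Class labels (character or factor), >= 2 classes present.
#' @param patients Patient id per row, grouping the inner folds.
#' @param C_grid Candidate penalty values.
#' @param seed Seed for the inner fold assignment.
#' @param n_inner Inner folds (default 5).
#' @return Object of class `hik_svm`: the support descriptors, per-pair
#'   binary machines, class list and chosen C.
#' @export
train_svm_ovo <- function(X, y, patients = seq_len(nrow(X)),
                          C_grid = 2^seq(-5, 15, by = 2), seed = 1,
                          n_inner = 5) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop_fmt("need at least 2 classes to train an SVM")
  if (length(C_grid) == 0) stop_fmt("C_grid must be nonempty")
  patients <- as.character(patients)

  C_best <- C_grid[1]
  if (length(C_grid) > 1) {
    pl <- patient_class_map(patients, y)
    n_use <- min(n_inner, length(pl))
    folds <- patient_stratified_folds(pl, n_folds = n_use, seed = seed)
    acc <- numeric(length(C_grid))
    for (ci in seq_along(C_grid)) {
      hits <- 0; total <- 0
      for (f in 0:(n_use - 1)) {
        te <- folds$assignment[patients] == f
        if (!any(te) || length(unique(y[!te])) < 2) next
        m <- ovo_fit(X[!te, , drop = FALSE], y[!te], C_grid[ci])
        pred <- ovo_predict(m, X[te, , drop = FALSE])
        hits <- hits + sum(pred == y[te]); total <- total + sum(te)
      }
      acc[ci] <- if (total > 0) hits / total else 0
    }
    best <- which(acc == max(acc))
    C_best <- min(C_grid[best])   # ties -> smallest C
  }
  m <- ovo_fit(X, y, C_best)
  m$C <- C_best
  m$C_grid <- C_grid
  m
}

# Fit all pairwise binary machines at a fixed C.
ovo_fit <- function(X, y, C) {
  classes <- sort(unique(y))
  K <- hik_gram(X)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    fit <- fit_binary_svm(K[idx, idx, drop = FALSE], y[idx], C)
    fit$idx <- idx
    fit$pair <- pr
    fit
  })
  structure(list(X = X, y = y, classes = classes, fits = fits, kernel = "HIK"),
            class = "hik_svm")
}

ovo_predict <- function(object, Xnew, details = FALSE) {
  classes <- object$classes
  votes <- matrix(0, nrow(Xnew), length(classes),
                  dimnames = list(NULL, classes))
  scores <- votes
  for (fit in object$fits) {
    Xp <- object$X[fit$idx, , drop = FALSE]
    Knew <- hik_gram(Xnew, Xp)[, fit$sv, drop = FALSE]
    d <- binary_decision(fit, Knew)           # positive -> second level
    a <- fit$levels[1]; b <- fit$levels[2]
    win <- ifelse(d > 0, b, a)
    votes[cbind(seq_len(nrow(Xnew)), match(win, classes))] <-
      votes[cbind(seq_len(nrow(Xnew)), match(win, classes))] + 1
    scores[, b] <- scores[, b] + d
    scores[, a] <- scores[, a] - d
  }
  pred <- character(nrow(Xnew))
  for (i in seq_len(nrow(Xnew))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      # vote tie: largest summed signed decision value, then lowest class index
      top <- top[order(-scores[i, top], top)][1]
    }
    pred[i] <- classes[top]
  }
  if (details) list(pred = pred, votes = votes, scores = scores) else pred
}

#' @export
print.hik_svm <- function(x, ...) {
  cat(sprintf("One-vs-one HIK-SVM: %d classes, %d training descriptors, C = %g\n",
              length(x$classes), nrow(x$X), x$C))
  invisible(x)
}

#' Predict with a one-vs-one HIK-SVM
#'
#' Each pairwise machine votes; the majority class wins. Vote ties are broken
#' by the largest sum of signed decision values, then by the lowest class
#' index.
#'
#' @param object A `hik_svm`.
#' @param newdata Matrix of descriptors (rows).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.hik_svm <- function(object, newdata, ...) {
  ovo_predict(object, newdata)
}

#' Sparse-representation classifier dictionary
#'
#' Stacks the L2-normalized training descriptors as dictionary columns.
#'
#' @param X n x d matrix of training descriptors (rows become columns).
#' @param y Labels per row.
#' @param T_sparsity OMP sparsity level (>= 1).
#' @return Object of class `src_model`.
#' @export
src_model <- function(X, y, T_sparsity = 30) {
  if (T_sparsity < 1) stop_fmt("sparsity level must be >= 1")
  A <- t(X)
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- 1
  A <- sweep(A, 2, nrm, "/")
  structure(list(A = A, labels = as.character(y),
                 T_sparsity = as.integer(T_sparsity)),
            class = "src_model")
}

# Orthogonal matching pursuit: greedily select up to T columns, refitting
# least squares on the chosen support each step. Ties toward lowest index.
omp_select <- function(x, A, T_sparsity) {
  support <- integer(0)
  beta <- numeric(0)
  r <- x
  for (t in seq_len(T_sparsity)) {
    corr <- abs(drop(crossprod(A, r)))
    corr[support] <- -Inf
    j <- which.max(corr)    # which.max takes the lowest index on ties
    support <- c(support, j)
    As <- A[, support, drop = FALSE]
    beta <- drop(qr.coef(qr(As), x))
    beta[is.na(beta)] <- 0
    r <- x - drop(As %*% beta)
    if (sqrt(sum(r^2)) < 1e-12) break
  }
  list(support = support, beta = beta, residual = r)
}

#' Classify by sparse representation (SRC)
#'
#' Solves a sparse approximation of the query over the training dictionary by
#' orthogonal matching pursuit with at most `T` atoms, then assigns the class
#' whose selected columns reconstruct the query with the smallest residual.
#' Ties go to the lowest class index.
#'
#' @param model A `src_model`.
#' @param x Query descriptor (same dimension as training descriptors).
#' @return Predicted label (character scalar).
#' @export
classify_src <- function(model, x) {
  A <- model$A
  if (length(x) != nrow(A)) stop_fmt("query dimension does not match dictionary")
  if (model$T_sparsity > ncol(A)) {
    stop_fmt("sparsity level T = %d exceeds dictionary size %d",
             model$T_sparsity, ncol(A))
  }
  sel <- omp_select(x, A, model$T_sparsity)
  classes <- sort(unique(model$labels))
  res <- vapply(classes, function(cl) {
    keep <- model$labels[sel$support] == cl
    approx <- if (any(keep)) {
      drop(A[, sel$support[keep], drop = FALSE] %*% sel$beta[keep])
    } else 0 * x
    sqrt(sum((x - approx)^2))
  }, numeric(1))
  classes[which.min(res)]
}

#' k-nearest-neighbour classification
#'
#' Majority label among the k Euclidean-nearest training descriptors. Label
#' ties are broken by the smallest mean distance to the query, then by the
#' lowest class index.
#'
#' @param train_X n x d matrix of training descriptors.
#' @param train_y Labels per row.
#' @param x Query descriptor, or a matrix of queries (rows).
#' @param k Number of neighbours (<= n).
#' @param metric `"euclidean"` (default) or `"hik"` (largest kernel
#'   similarity instead of smallest distance).
#' @return Predicted label(s).
#' @export
classify_knn <- function(train_X, train_y, x, k, metric = c("euclidean", "hik")) {
  metric <- match.arg(metric)
  if (k > nrow(train_X)) stop_fmt("k exceeds the number of training points")
  X <- if (is.matrix(x)) x else matrix(x, 1)
  train_y <- as.character(train_y)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- if (metric == "euclidean") sqrt(sqdist(X[i, , drop = FALSE], train_X)[1, ])
         else -hik_gram(X[i, , drop = FALSE], train_X)[1, ]
    nn <- order(d)[seq_len(k)]
    tab <- table(train_y[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      md <- vapply(top, function(cl) mean(d[nn][train_y[nn] == cl]), numeric(1))
      top <- top[order(md, top)][1]
    }
    out[i] <- top[1]
  }
  if (is.matrix(x)) out else out[1]
}
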