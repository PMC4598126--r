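test_that("patient-stratified folds balance classes and never split a patient", {
  # 15 patients, 5 per class, 5 folds: exactly one patient per class per fold
  pl <- setNames(rep(c("m", "g", "p"), each = 5), paste0("P", 1:15))
  f <- patient_stratified_folds(pl, n_folds = 5, seed = 1)
  for (cl in c("m", "g", "p")) {
    expect_equal(as.integer(table(f$assignment[names(pl)[pl == cl]])), rep(1L, 5))
  }

  # 233 patients in realistic class proportions: fold sizes in {46, 47}
  pl233 <- setNames(c(rep("meningioma", 82), rep("glioma", 89), rep("pituitary", 62)),
                    sprintf("Q%03d", 1:233))
  f233 <- patient_stratified_folds(pl233, n_folds = 5, seed = 7)
  sizes <- table(f233$assignment)
  expect_true(all(sizes %in% c(46, 47)))
  # per-class counts per fold differ by <= 1
  for (cl in unique(pl233)) {
    tab <- table(f233$assignment[names(pl233)[pl233 == cl]])
    expect_lte(max(tab) - min(tab), 1)
  }
  # every patient in exactly one fold
  expect_equal(sort(names(f233$assignment)), sort(names(pl233)))
  expect_true(all(f233$assignment %in% 0:4))

  # fold sizes per class are invariant to patient relabeling
  pl2 <- setNames(pl233, sprintf("Z%03d", 233:1))
  f2 <- patient_stratified_folds(pl2, n_folds = 5, seed = 7)
  expect_equal(sort(table(f2$assignment)), sort(table(f233$assignment)))

  w <- testthat::capture_warnings(
    patient_stratified_folds(setNames(c("a", "a", "b"), 1:3), 5, 1))
  expect_true(all(grepl("only", w)))
  expect_length(w, 2)  # both classes are short of patients
})

test_that("patients with conflicting slice labels get the majority label with a warning", {
  expect_warning(
    m <- patient_class_map(c("p1", "p1", "p1", "p2"), c("A", "B", "B", "A")),
    "majority")
  expect_equal(unname(m["p1"]), "B")
  expect_equal(unname(m["p2"]), "A")
})

test_that("sensitivity/specificity reproduce printed reference values and the identity case", {
  # reference confusion matrix for a three-class intensity-histogram run
  cm <- matrix(c(428, 36, 244,
                 37, 1262, 127,
                 240, 192, 498), 3, 3, byrow = TRUE,
               dimnames = list(c("meningioma", "glioma", "pituitary"),
                               c("meningioma", "glioma", "pituitary")))
  ss <- sensitivity_specificity(cm)
  expect_equal(unname(ss$sensitivity["meningioma"]), 60.5)
  expect_equal(unname(ss$specificity["meningioma"]), 88.2)
  expect_equal(unname(ss$sensitivity), c(60.5, 88.5, 53.5))
  expect_equal(unname(ss$specificity), c(88.2, 86.1, 82.6))

  id <- diag(c(10, 20, 30))
  ssi <- sensitivity_specificity(id)
  expect_equal(unname(ssi$sensitivity), rep(100, 3))
  expect_equal(unname(ssi$specificity), rep(100, 3))
  expect_equal(ssi$accuracy, 100)

  z <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)  # class 1 has no true slices
  expect_warning(ssz <- sensitivity_specificity(z), "undefined")
  expect_true(is.nan(ssz$sensitivity[1]))
  expect_error(sensitivity_specificity(matrix(1, 2, 3)), "square")
})

test_that("regularized LDA finds the separating axis and matches a symmetric eigensolver", {
  set.seed(30)
  X <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
             matrix(rnorm(100, 0, 0.5), 50, 2) + matrix(c(5, 0), 50, 2, byrow = TRUE))
  y <- rep(c("a", "b"), each = 50)
  pr <- lda_project_2d(X, y)
  v1 <- pr$basis[, 1] / sqrt(sum(pr$basis[, 1]^2))
  expect_gt(abs(v1[1]), 0.99)  # first direction along e1

  # 3 classes: rank(Sb) <= 2, so the third generalized eigenvalue vanishes
  X3 <- matrix(rnorm(300), 100, 3)
  y3 <- sample(c("a", "b", "c"), 100, replace = TRUE)
  pr3 <- lda_project_2d(X3, y3, lam = 1e-3)
  expect_equal(dim(pr3$coords), c(100, 2))

  # eigenpairs match the symmetric-reduction oracle (Cholesky whitening)
  d <- ncol(X3)
  mu <- colMeans(X3); Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (cl in unique(y3)) {
    Xc <- X3[y3 == cl, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(Xc, 2, colMeans(Xc)))
    Sb <- Sb + nrow(Xc) * tcrossprod(colMeans(Xc) - mu)
  }
  lam <- 1e-3
  U <- chol(Sw + lam * diag(d))      # Sw + lam I = U'U, whiten with U^-T
  A <- solve(t(U), Sb)
  Mst <- t(solve(t(U), t(A)))        # U^-T Sb U^-1, symmetric
  ev <- eigen((Mst + t(Mst)) / 2, symmetric = TRUE)
  expect_equal(pr3$eigenvalues, ev$values[1:2], tolerance = 1e-8)

  expect_error(lda_project_2d(X3, y3, lam = 0), "lam")
  expect_error(lda_project_2d(X3, rep("a", 100)), "2 classes")
})

test_that("cross-validation is leak-free by construction, deterministic, and aggregates correctly", {
  man <- tiny_phantom()
  cfg <- fast_config(feature = "histogram", G = 10, R = 0, L = 0, n_folds = 3)
  cv1 <- suppressWarnings(cross_validate(man, cfg, seed = 4))
  cv2 <- suppressWarnings(cross_validate(man, cfg, seed = 4))
  expect_identical(cv1$pooled_cm, cv2$pooled_cm)  # same seed, same report
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)

  # pooled matrix is the elementwise sum of fold matrices; rows = slice counts
  expect_equal(cv1$pooled_cm, Reduce(`+`, cv1$per_fold_cm))
  expect_equal(unname(rowSums(cv1$pooled_cm)),
               as.numeric(table(factor(man$records$label, levels = man$classes))))
  expect_equal(cv1$pooled_accuracy, sum(diag(cv1$pooled_cm)) / sum(cv1$pooled_cm))

  # no patient straddles folds
  fold_of <- cv1$folds$assignment[man$records$patient_id]
  expect_true(all(tapply(fold_of, man$records$patient_id,
                         function(v) length(unique(v))) == 1))

  # paired comparisons can share identical folds
  cv3 <- suppressWarnings(cross_validate(man, update_config(cfg, R = 4),
                                         seed = 4, folds = cv1$folds))
  expect_identical(cv3$folds$assignment, cv1$folds$assignment)
})

test_that("the fitted model object supports print, summary, predict and report writing", {
  man <- tiny_phantom()
  cfg <- fast_config(feature = "histogram", G = 10, R = 0, L = 0, n_folds = 3)
  fit <- ringspm(man, cfg)
  expect_s3_class(fit, "ringspm")
  expect_output(print(fit), "histogram")
  expect_output(summary(fit), "training accuracy")
  pred <- predict(fit, man)
  expect_length(pred, nrow(man$records))
  expect_true(all(pred %in% man$classes))

  cv <- suppressWarnings(cross_validate(man, cfg, seed = 4))
  stem <- tempfile()
  write_report(cv, stem)
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$mean_accuracy, cv$mean_accuracy)
  expect_true(file.exists(paste0(stem, ".md")))
})
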