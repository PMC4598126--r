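test_that("the histogram intersection kernel and its Gram matrix behave as a Mercer kernel", {
  x <- c(0.2, 0.8); y <- c(0.5, 0.5)
  expect_equal(hik(x, y), 0.7)
  expect_equal(hik(x, x), sum(x))               # self-kernel is the L1 mass
  expect_equal(hik(c(1, 0), c(0, 1)), 0)        # disjoint supports
  expect_equal(hik(x, y), hik(y, x))
  expect_error(hik(c(-1, 0), c(0, 1)), "nonnegative")

  set.seed(20)
  X <- matrix(runif(200), 20, 10)
  K <- hik_gram(X)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # hik(x, y) <= min(hik(x,x), hik(y,y))
  for (i in 1:5) for (j in 1:5) {
    expect_lte(K[i, j], min(K[i, i], K[j, j]) + 1e-12)
  }
  # Gram equals the scalar kernel entrywise
  expect_equal(K[3, 7], hik(X[3, ], X[7, ]))
})

# Three HIK-separable descriptor clusters with patient structure.
make_sep_data <- function(n_per = 12, seed = 1) {
  set.seed(seed)
  protos <- rbind(c(8, 1, 1, 0, 0, 0), c(0, 0, 8, 1, 1, 0), c(1, 0, 0, 0, 8, 1))
  X <- NULL; y <- NULL; pat <- NULL
  for (c in 1:3) {
    for (i in 1:n_per) {
      X <- rbind(X, pmax(protos[c, ] + runif(6, 0, 0.3), 0))
      y <- c(y, LETTERS[c])
      pat <- c(pat, sprintf("%s%d", LETTERS[c], (i - 1) %/% 2))
    }
  }
  list(X = X, y = y, patients = pat)
}

test_that("the one-vs-one HIK-SVM separates separable data and is deterministic", {
  d <- make_sep_data()
  m <- train_svm_ovo(d$X, d$y, d$patients, C_grid = c(1, 10), seed = 3)
  expect_s3_class(m, "hik_svm")
  expect_true(m$C %in% c(1, 10))
  expect_equal(predict(m, d$X), d$y)  # training accuracy 100%

  m2 <- train_svm_ovo(d$X, d$y, d$patients, C_grid = c(1, 10), seed = 3)
  expect_identical(predict(m2, d$X), predict(m, d$X))
  expect_identical(m2$C, m$C)

  # held-out points from the same clusters classify correctly
  dt <- make_sep_data(seed = 99)
  expect_equal(predict(m, dt$X), dt$y)

  expect_error(train_svm_ovo(d$X[1:12, ], d$y[1:12], d$patients[1:12]),
               "at least 2 classes")
})

test_that("one-vs-one prediction equals the brute-force pairwise voting rule", {
  d <- make_sep_data(n_per = 8, seed = 5)
  m <- train_svm_ovo(d$X, d$y, d$patients, C_grid = 10)
  dt <- make_sep_data(n_per = 4, seed = 6)
  det <- ringspm:::ovo_predict(m, dt$X, details = TRUE)
  # recompute the vote from each pair's decision sign
  for (i in seq_len(nrow(dt$X))) {
    votes <- setNames(numeric(3), m$classes)
    for (fit in m$fits) {
      Xp <- m$X[fit$idx, , drop = FALSE]
      dv <- ringspm:::binary_decision(fit, hik_gram(dt$X[i, , drop = FALSE], Xp)[, fit$sv, drop = FALSE])
      w <- if (dv > 0) fit$levels[2] else fit$levels[1]
      votes[w] <- votes[w] + 1
    }
    expect_equal(unname(det$votes[i, ]), unname(votes))
    expect_equal(det$pred[i], names(which.max(votes)))
  }
})

test_that("SRC with OMP matches zero-residual and exhaustive-search oracles", {
  set.seed(7)
  # orthogonal dictionary: greedy OMP is provably optimal, so residuals must
  # match exhaustive search over all supports
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:8]
  X <- t(Q)                      # 8 training descriptors, dim 8
  y <- rep(c("a", "b"), each = 4)
  mod <- src_model(X, y, T_sparsity = 3)

  # query equal to a training column -> its label, zero residual
  expect_equal(classify_src(mod, Q[, 2]), "a")
  expect_equal(classify_src(mod, Q[, 7]), "b")

  # T = 1: label of the max-|inner product| column
  mod1 <- src_model(X, y, T_sparsity = 1)
  x <- rnorm(8)
  best <- which.max(abs(drop(crossprod(mod1$A, x))))
  expect_equal(classify_src(mod1, x), y[best])

  # OMP support/residual vs exhaustive search over supports of size <= T
  for (trial in 1:5) {
    x <- rnorm(8)
    sel <- ringspm:::omp_select(x, mod$A, 3)
    combs <- combn(8, 3, simplify = FALSE)
    res_best <- min(vapply(combs, function(s) {
      beta <- qr.coef(qr(mod$A[, s, drop = FALSE]), x)
      sqrt(sum((x - mod$A[, s, drop = FALSE] %*% beta)^2))
    }, numeric(1)))
    expect_equal(sqrt(sum(sel$residual^2)), res_best, tolerance = 1e-9)
  }

  expect_error(classify_src(src_model(X, y, T_sparsity = 9), rnorm(8)), "sparsity")
  expect_error(classify_src(mod, rnorm(5)), "dimension")
})

test_that("kNN classification matches an exhaustive distance sort with the stated tie rules", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  y <- c("A", "A", "A", "B", "B", "B")
  expect_equal(classify_knn(X, y, c(0, 0), k = 1), "A")   # exact training point
  expect_equal(classify_knn(X, y, c(5, 5), k = 3), "B")

  # neighbours (A, A, B) -> majority A
  expect_equal(classify_knn(X, y, c(0.4, 0.4), k = 3), "A")

  # vote tie at k=2: class with the smaller mean distance wins
  expect_equal(classify_knn(rbind(c(0, 0), c(3, 0)), c("A", "B"), c(1, 0), k = 2), "A")

  set.seed(8)
  Xr <- matrix(runif(60), 30, 2)
  yr <- sample(c("A", "B", "C"), 30, replace = TRUE)
  for (trial in 1:10) {
    q <- runif(2)
    d <- sqrt(colSums((t(Xr) - q)^2))
    nn <- order(d)[1:5]
    tab <- table(yr[nn])
    got <- classify_knn(Xr, yr, q, k = 5)
    expect_true(got %in% names(tab)[tab == max(tab)])
  }
  expect_error(classify_knn(X, y, c(0, 0), k = 10), "exceeds")
})
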