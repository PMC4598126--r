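test_that("intensity histograms count and normalize correctly", {
  lev <- matrix(c(0L, 0L, 1L, 2L), 2, 2)
  full <- matrix(TRUE, 2, 2)
  expect_equal(intensity_histogram(lev, full, G = 3), c(0.5, 0.25, 0.25))

  const <- matrix(2L, 3, 3)
  h <- intensity_histogram(const, matrix(TRUE, 3, 3), G = 5)
  expect_equal(h, c(0, 0, 1, 0, 0))  # one-hot at the constant level

  expect_equal(intensity_histogram(lev, matrix(FALSE, 2, 2), G = 3), c(0, 0, 0))
})

test_that("isotropic GLCM matches the hand-enumerated 2x2 case and the pair-scan oracle", {
  # image rows (0,1),(0,1): 12 symmetric directed pairs across 4 directions
  lev <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  g <- glcm_isotropic(lev, matrix(TRUE, 2, 2), G = 2, D = 1)
  expect_true(g$normalized)
  expect_equal(g$P, matrix(c(1/6, 1/3, 1/3, 1/6), 2, 2))

  # constant region: all mass at (g, g)
  gc <- glcm_isotropic(matrix(1L, 4, 4), matrix(TRUE, 4, 4), G = 3, D = 1)
  expect_equal(gc$P[2, 2], 1)

  # exhaustive pair-enumeration oracle on random regions up to 32x32
  set.seed(3)
  for (trial in 1:4) {
    n <- sample(8:32, 1)
    G <- sample(c(4, 8), 1); D <- sample(1:3, 1)
    lev <- matrix(sample(0:(G - 1), n * n, replace = TRUE), n, n)
    region <- matrix(runif(n * n) < 0.6, n, n)
    if (!any(region)) region[1, 1] <- TRUE
    got <- glcm_isotropic(lev, region, G = G, D = D)
    expect_equal(got$P, brute_glcm_isotropic(lev, region, G, D))
    expect_equal(got$P, t(got$P))  # symmetric
    if (got$normalized) expect_equal(sum(got$P), 1, tolerance = 1e-9)
  }

  # region admitting no pair: zero matrix flagged unnormalized
  lone <- matrix(FALSE, 5, 5); lone[3, 3] <- TRUE
  g0 <- glcm_isotropic(matrix(0L, 5, 5), lone, G = 2, D = 1)
  expect_false(g0$normalized)
  expect_true(all(g0$P == 0))
})

test_that("isotropic GLCM is invariant under joint 90-degree rotation", {
  set.seed(4)
  lev <- matrix(sample(0:4, 144, replace = TRUE), 12, 12)
  region <- matrix(runif(144) < 0.7, 12, 12)
  rot <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  a <- glcm_isotropic(lev, region, G = 5, D = 2)$P
  b <- glcm_isotropic(rot(lev), rot(region), G = 5, D = 2)$P
  expect_equal(a, b)
})

test_that("GLCM-element vectors take the lower triangle in row-major order", {
  g <- structure(list(P = matrix(c(1/6, 1/3, 1/3, 1/6), 2, 2), G = 2, D = 1,
                      normalized = TRUE), class = "glcm")
  expect_equal(glcm_element_features(g), c(1/6, 1/3, 1/6))

  for (G in c(10, 20, 40)) {
    P <- matrix(1 / G^2, G, G)
    gg <- structure(list(P = P, G = G, D = 1, normalized = TRUE), class = "glcm")
    expect_length(glcm_element_features(gg), G * (G + 1) / 2)
  }
  # ordering: P(0,0), P(1,0), P(1,1), P(2,0), ...
  P <- matrix(0, 3, 3); P[lower.tri(P, diag = TRUE)] <- 1:6
  P <- P + t(P) - diag(diag(P))
  gg <- structure(list(P = P / sum(P), G = 3, D = 1, normalized = TRUE), class = "glcm")
  expect_equal(glcm_element_features(gg) * sum(P), c(1, 2, 4, 3, 5, 6))

  asym <- structure(list(P = matrix(c(0.5, 0.2, 0.3, 0), 2, 2), G = 2, D = 1,
                         normalized = TRUE), class = "glcm")
  expect_error(glcm_element_features(asym), "symmetric")
})

test_that("Haralick statistics follow their closed forms", {
  mk_glcm <- function(P) structure(list(P = P, G = nrow(P), D = 1, normalized = TRUE),
                                   class = "glcm")
  # diagonal GLCM: contrast 0, homogeneity 1
  s <- glcm_statistics(mk_glcm(diag(c(0.3, 0.3, 0.4))))
  expect_equal(unname(s["contrast"]), 0)
  expect_equal(unname(s["homogeneity"]), 1)
  # uniform GLCM: energy 1/G^2
  G <- 6
  s <- glcm_statistics(mk_glcm(matrix(1 / G^2, G, G)))
  expect_equal(unname(s["energy"]), 1 / G^2)
  # hand case: contrast = 2 * 1 * (1/3)
  s <- glcm_statistics(mk_glcm(matrix(c(1/6, 1/3, 1/3, 1/6), 2, 2)))
  expect_equal(unname(s["contrast"]), 2 / 3)
  # degenerate marginals: correlation defined as 0
  s <- glcm_statistics(mk_glcm(diag(c(1, 0))))
  expect_equal(unname(s["correlation"]), 0)

  g <- glcm_isotropic(matrix(0L, 3, 3), matrix(c(TRUE, rep(FALSE, 8)), 3, 3), G = 2)
  expect_error(glcm_statistics(g), "normalized")
})

test_that("the 16-feature per-direction vector is compositional", {
  set.seed(5)
  lev <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  region <- matrix(TRUE, 10, 10)
  v <- glcm_statistics_16(lev, region, G = 4, D = 1)
  expect_length(v, 16)

  # each direction's block equals glcm_statistics on that direction's matrix
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (d in seq_along(offs)) {
    C <- ringspm:::glcm_direction_counts(lev, region, 4, offs[[d]][1], offs[[d]][2])
    g <- structure(list(P = C / sum(C), G = 4, D = 1, normalized = TRUE), class = "glcm")
    expect_equal(v[(4 * d - 3):(4 * d)], unname(glcm_statistics(g)))
  }

  # constant region: contrast features 0, homogeneity features 1
  vc <- glcm_statistics_16(matrix(2L, 8, 8), matrix(TRUE, 8, 8), G = 4, D = 1)
  expect_equal(vc[c(1, 5, 9, 13)], rep(0, 4))
  expect_equal(vc[c(4, 8, 12, 16)], rep(1, 4))

  # a direction with no pairs contributes zeros with a warning
  row1 <- matrix(FALSE, 5, 5); row1[3, ] <- TRUE
  w <- testthat::capture_warnings(
    v1 <- glcm_statistics_16(matrix(0L, 5, 5), row1, G = 2, D = 1))
  expect_true(all(grepl("no co-occurring", w)))
  expect_length(w, 3)  # the three non-horizontal directions are empty
  expect_equal(v1[5:8], rep(0, 4))  # 45-degree block empty for a 1-pixel-high region
})
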