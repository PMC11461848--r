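test_that("fit_cca matches the independent whitening+SVD oracle", {
  set.seed(7)
  A <- matrix(rnorm(500 * 10), 500)
  B <- matrix(rnorm(500 * 10), 500)
  B[, 1:3] <- B[, 1:3] + A[, 1:3]
  m <- fit_cca(A, B, lambda = 0)
  o <- cca_oracle_svd(A, B)
  expect_lt(max(abs(m$correlations - o$cor[seq_len(m$d)])), 1e-8)
  # variates agree up to per-component sign
  sgn <- sign(colSums(o$variates_A[, seq_len(m$d)] * m$variates$A))
  expect_lt(max(abs(m$variates$A -
                      sweep(o$variates_A[, seq_len(m$d)], 2, sgn, `*`))), 1e-7)
})

test_that("identical views and 1-D views recover the closed forms", {
  set.seed(8)
  A <- matrix(rnorm(200 * 6), 200)
  mi <- fit_cca(A, A, lambda = 0)
  expect_lt(max(abs(mi$correlations - 1)), 1e-6)

  a <- matrix(rnorm(100), 100)
  b <- matrix(0.6 * a + rnorm(100), 100)
  m1 <- fit_cca(a, b, lambda = 0)
  expect_equal(m1$correlations, abs(cor(a, b)[1, 1]), tolerance = 1e-10)
})

test_that("training variates satisfy the CCA constraints", {
  set.seed(9)
  g <- gen_dual_view_features(dual_view_config(400, 8, 6, 3, seed = 4))
  m <- fit_cca(g$A, g$B, lambda = 0)
  expect_true(all(diff(m$correlations) <= 1e-12)) # non-increasing
  expect_true(all(m$correlations >= 0 & m$correlations <= 1 + 1e-9))
  expect_equal(apply(m$variates$A, 2, var), rep(1, m$d), tolerance = 1e-6)
  expect_equal(apply(m$variates$B, 2, var), rep(1, m$d), tolerance = 1e-6)
  # cross-view correlation per component equals the stored value
  cc <- diag(cor(m$variates$A, m$variates$B))
  expect_equal(cc, m$correlations, tolerance = 1e-6)
  # distinct components uncorrelated within each view
  off <- cor(m$variates$A)[upper.tri(diag(m$d))]
  expect_lt(max(abs(off)), 1e-6)
  # sign convention: first nonzero loading of each W_A column positive
  firsts <- apply(m$W_A, 2, function(w) w[which(abs(w) > 1e-12)[1]])
  expect_true(all(firsts > 0))
})

test_that("fuse produces Z1 (width 2d) and Z2 (width d) consistently", {
  set.seed(10)
  g <- gen_dual_view_features(dual_view_config(150, 12, 10, 4, seed = 5))
  m <- fit_cca(g$A, g$B, lambda = 0, d = 10)
  z1 <- fuse(m, g$A, g$B, "Z1_concat")
  z2 <- fuse(m, g$A, g$B, "Z2_sum")
  expect_equal(ncol(z1), 2L * m$d)
  expect_equal(ncol(z2), m$d)
  # fusing the training data reproduces the stored variates
  expect_lt(max(abs(z1[, seq_len(m$d)] - m$variates$A)), 1e-10)
  expect_lt(max(abs(z2 - (m$variates$A + m$variates$B))), 1e-10)
  expect_error(fuse(m, g$A[, 1:5], g$B, "Z1_concat"), "dimension mismatch")
})

test_that("shrinkage handles p > n and PCA pre-reduction matches full fit", {
  set.seed(11)
  n <- 40
  A <- matrix(rnorm(n * 120), n)
  B <- matrix(rnorm(n * 90), n)
  m <- fit_cca(A, B, lambda = 1e-3, pca_rank = n - 1)
  expect_true(all(is.finite(m$correlations)))
  expect_lte(m$d, n - 1)
  expect_equal(dim(m$W_A), c(120L, m$d)) # composed back to input space

  # on a full-rank small problem PCA pre-reduction is a no-op
  A2 <- matrix(rnorm(200 * 6), 200)
  B2 <- matrix(rnorm(200 * 5), 200)
  f_full <- fit_cca(A2, B2, lambda = 0)
  f_pca <- fit_cca(A2, B2, lambda = 0, pca_rank = 150)
  expect_equal(f_full$correlations, f_pca$correlations, tolerance = 1e-8)
})

test_that("adding noise to one view does not increase the leading correlation", {
  deltas <- vapply(1:10, function(s) {
    g <- gen_dual_view_features(dual_view_config(300, 6, 6, 2, seed = s))
    base <- fit_cca(g$A, g$B, lambda = 0)$correlations[1]
    noisy <- neurofuse:::with_seed(1000 + s, {
      Bn <- g$B + matrix(rnorm(length(g$B), sd = 1), nrow(g$B))
      fit_cca(g$A, Bn, lambda = 0)$correlations[1]
    })
    noisy - base
  }, 0)
  expect_true(mean(deltas < 0) >= 0.9) # statistical: noise hurts
  expect_lt(mean(deltas), 0)
})

test_that("fit_cca validates its inputs", {
  A <- matrix(rnorm(20), 10)
  expect_error(fit_cca(A, matrix(rnorm(18), 9)), "same number of samples")
  expect_error(fit_cca(A[1:2, , drop = FALSE], A[1:2, , drop = FALSE]),
               "at least 3")
  Abad <- A; Abad[1] <- NA
  expect_error(fit_cca(Abad, A), "non-finite")
})

test_that("CCA archives serialize to plain text", {
  g <- gen_dual_view_features(dual_view_config(50, 4, 4, 2, seed = 6))
  m <- fit_cca(g$A, g$B)
  dir <- tempfile("cca")
  write_cca_archive(m, dir)
  expect_true(all(file.exists(file.path(dir, c("W_A.csv", "W_B.csv",
                                               "meta.json")))))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$correlations, m$correlations, tolerance = 1e-12)
})
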