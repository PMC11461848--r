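test_that("gen_volumes honours balance, determinism and the noiseless contract", {
  cfg <- phantom_config(12L, shape = c(12L, 12L, 12L), seed = 7L)
  vols <- gen_volumes(cfg)
  expect_length(vols, 12L)
  labs <- vapply(vols, function(v) v$label, integer(1))
  expect_equal(as.vector(table(labs)), c(4L, 4L, 4L))

  # identical config + seed -> bit-identical voxels
  vols2 <- gen_volumes(cfg)
  expect_identical(lapply(vols, `[[`, "voxels"), lapply(vols2, `[[`, "voxels"))

  # noiseless, jitter-free: within-class volumes identical, between-class
  # nucleus means differ by exactly the configured deltas
  cfg0 <- phantom_config(6L, shape = c(16L, 16L, 16L), noise_sd = 0,
                         jitter_voxels = 0L,
                         class_intensity_deltas = c(0, 0.4, 0.9),
                         class_radius_scales = c(1, 1, 1), seed = 3L)
  v0 <- gen_volumes(cfg0)
  l0 <- vapply(v0, function(v) v$label, integer(1))
  for (k in 0:2) {
    same <- which(l0 == k)
    expect_identical(v0[[same[1]]]$voxels, v0[[same[2]]]$voxels)
  }
  nuc <- neurofuse:::ellipsoid_mask(cfg0$shape, cfg0$nucleus_center,
                                    cfg0$nucleus_radii)
  means <- vapply(0:2, function(k) mean(v0[[which(l0 == k)[1]]]$voxels[nuc]), 0)
  expect_equal(means - means[1], c(0, 0.4, 0.9), tolerance = 1e-12)
})

test_that("phantom_config rejects invalid settings", {
  expect_error(phantom_config(2L, n_classes = 3L), "n_samples")
  expect_error(phantom_config(9L, shape = c(12L, 12L)), "shape")
  expect_error(phantom_config(9L, noise_sd = -1), "noise_sd")
})

test_that("dual-view generator returns closed-form population correlations", {
  g0 <- gen_dual_view_features(dual_view_config(50, 6, 5, 2, noise_sd = 0,
                                                seed = 1))
  expect_equal(g0$theoretical_correlations[1:2], c(1, 1))
  expect_equal(g0$theoretical_correlations[3:5], c(0, 0, 0))

  gind <- gen_dual_view_features(dual_view_config(50, 6, 5, 0, seed = 1))
  expect_equal(gind$theoretical_correlations, rep(0, 5))

  expect_error(dual_view_config(50, 4, 5, 5), "d_latent")

  # closed form rho_j = s_j^2 / (s_j^2 + sigma^2), s_j = scale / sqrt(j)
  cfg <- dual_view_config(100, 8, 7, 3, loading_scale = 2, noise_sd = 0.5,
                          seed = 2)
  g <- gen_dual_view_features(cfg)
  s <- 2 / sqrt(1:3)
  expect_equal(g$theoretical_correlations[1:3], s^2 / (s^2 + 0.25))
})

test_that("empirical canonical correlations converge to theory with n", {
  cfg_small <- dual_view_config(200, 5, 5, 2, seed = 9)
  cfg_big <- dual_view_config(2000, 5, 5, 2, seed = 9)
  g_s <- gen_dual_view_features(cfg_small)
  g_b <- gen_dual_view_features(cfg_big)
  est_s <- fit_cca(g_s$A, g_s$B, lambda = 0)$correlations[1:2]
  est_b <- fit_cca(g_b$A, g_b$B, lambda = 0)$correlations[1:2]
  theo <- g_b$theoretical_correlations[1:2]
  expect_lt(max(abs(est_b - theo)), 0.05)
  expect_lt(max(abs(est_s - theo)), 0.2)
  # averaged over seeds, the large-n error is smaller than the small-n error
  errs <- vapply(1:3, function(s) {
    gs <- gen_dual_view_features(dual_view_config(200, 5, 5, 2, seed = 20 + s))
    gb <- gen_dual_view_features(dual_view_config(2000, 5, 5, 2, seed = 20 + s))
    th <- gb$theoretical_correlations[1:2]
    c(max(abs(fit_cca(gs$A, gs$B, lambda = 0)$correlations[1:2] - th)),
      max(abs(fit_cca(gb$A, gb$B, lambda = 0)$correlations[1:2] - th)))
  }, c(0, 0))
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("planted problems put signal only in the informative set", {
  pb <- gen_planted_selection(300, 100, 10, effect_size = 2, seed = 1)
  expect_length(pb$informative_set, 10L)
  expect_true(all(diff(sort(as.vector(table(pb$y)))) <= 1))
  pb2 <- gen_planted_selection(300, 100, 10, effect_size = 2, seed = 1)
  expect_identical(pb$X, pb2$X)
  expect_identical(pb$y, pb2$y)
  expect_error(gen_planted_selection(50, 10, 10, 1, 1), "k_informative")

  # effect 0: KNN accuracy at chance on any subset
  pb0 <- gen_planted_selection(300, 30, 5, effect_size = 0, seed = 2)
  rep0 <- kfold_evaluate(pb0$X, pb0$y, "knn", k = 5, seed = 1)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / 300)
  expect_lt(abs(rep0$mean[["accuracy"]] - 1 / 3), se3)
})

test_that("permuting labels destroys the planted association", {
  pb <- locked_planted_problem(seed = 3L)
  cols_S <- pb$informative_set
  acc_true <- kfold_evaluate(pb$X[, cols_S], pb$y, "knn", k = 5,
                             seed = 1)$mean[["accuracy"]]
  expect_gt(acc_true, 0.6) # genuine signal present
  accs <- neurofuse:::with_seed(11, replicate(20, {
    yp <- sample(pb$y)
    kfold_evaluate(pb$X[, cols_S], yp, "knn", k = 5, seed = 1)$mean[["accuracy"]]
  }))
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / length(pb$y))
  expect_lt(abs(mean(accs) - 1 / 3), se3)
  expect_true(all(accs < acc_true))
})

test_that("feature CSV round-trips matrices and labels", {
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- c(0L, 1L, 2L, 0L, 1L)
  path <- tempfile(fileext = ".csv")
  write_feature_csv(X, path, y)
  back <- read_feature_csv(path)
  expect_equal(back$X, X, tolerance = 1e-12)
  expect_identical(back$y, y)
})
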