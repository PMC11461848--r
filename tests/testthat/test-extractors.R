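test_that("variant-3 manifest has 2+3+2 convolutions, 3 pools and 1000-wide taps", {
  spec <- build_extractor("cnn_variant3")
  kinds <- vapply(spec$layers, `[[`, "", "kind_name")
  # convolutions grouped by pooling stage
  pools <- which(kinds == "maxpool")
  expect_length(pools, 3L)
  groups <- split(which(kinds == "conv"),
                  findInterval(which(kinds == "conv"), pools))
  expect_equal(lengths(groups, use.names = FALSE), c(2L, 3L, 2L))
  expect_setequal(names(spec$tap_points), c("FC1", "FC2"))
  for (tap in spec$tap_points)
    expect_equal(spec$layers[[tap]]$c_out, 1000L)
  expect_equal(kinds[length(kinds)], "softmax")
})

test_that("resnet15 manifest has 5 stages of 3 two-convolution residual units", {
  spec <- build_extractor("resnet15", c(32L, 32L, 32L), base_width = 4L)
  kinds <- vapply(spec$layers, `[[`, "", "kind_name")
  expect_equal(sum(kinds == "res_save"), 15L) # 5 stages x 3 units
  expect_equal(sum(kinds == "res_add"), 15L)
  expect_equal(sum(kinds == "maxpool"), 5L)
  # each unit: exactly 2 convolutions between save and add
  saves <- which(kinds == "res_save")
  adds <- which(kinds == "res_add")
  for (u in seq_along(saves))
    expect_equal(sum(kinds[saves[u]:adds[u]] == "conv"), 2L)
  # initial conv blocks before the first residual stage
  expect_equal(sum(kinds[seq_len(saves[1] - 1)] == "conv"), 2L)
  expect_equal(names(spec$tap_points), "FC4")
  expect_equal(spec$layers[[spec$tap_points[["FC4"]]]]$c_out, 1000L)
})

test_that("build_extractor rejects unknown kinds and incompatible shapes", {
  expect_error(build_extractor("vgg"), "unknown extractor kind")
  expect_error(build_extractor("cnn_variant3", c(4L, 4L, 4L)),
               "incompatible input shape")
})

test_that("fc_concat_max is an element-wise max with the equality rule", {
  expect_equal(fc_concat_max(c(1, 3, 2), c(2, 1, 4)), c(2, 3, 4))
  x <- rnorm(10)
  expect_equal(fc_concat_max(x, x), x) # shared values taken once
  expect_error(fc_concat_max(c(1, 2), c(1, 2, 3)), "length mismatch")
  # properties: dominance, commutativity, idempotence
  a <- rnorm(50); b <- rnorm(50)
  m <- fc_concat_max(a, b)
  expect_true(all(m >= a & m >= b))
  expect_equal(m, fc_concat_max(b, a))
  expect_equal(fc_concat_max(m, m), m)
})

test_that("epochs = 0 returns an initialized, untrained model", {
  cfg <- phantom_config(6L, shape = c(8L, 8L, 8L), seed = 1L)
  vols <- lapply(gen_volumes(cfg), preprocess_volume, c(8L, 8L, 8L))
  spec <- build_extractor("cnn_variant3", c(8L, 8L, 8L), base_width = 2L)
  m <- train_extractor(spec, vols, train_config(epochs = 0L, seed = 1L))
  expect_false(m$trained)
  expect_equal(nrow(m$history), 0L)
  p0 <- neurofuse:::init_extractor_params(spec,
                                          neurofuse:::derive_seed(1L, 2L))
  expect_identical(m$params, p0) # no weights updated
})

test_that("training is deterministic and validates its inputs", {
  cfg <- phantom_config(9L, shape = c(8L, 8L, 8L), noise_sd = 0.05, seed = 2L)
  vols <- lapply(gen_volumes(cfg), preprocess_volume, c(8L, 8L, 8L))
  spec <- build_extractor("cnn_variant3", c(8L, 8L, 8L), base_width = 2L)
  tc <- train_config(epochs = 2L, batch_size = 4L, seed = 5L)
  m1 <- train_extractor(spec, vols, tc)
  m2 <- train_extractor(spec, vols, tc)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$params, m2$params)

  expect_error(train_extractor(spec, list(), tc), "empty data")
  one_class <- vols
  for (i in seq_along(one_class)) one_class[[i]]$label <- 0L
  expect_error(train_extractor(spec, one_class, tc), "single-class")
})

test_that("extract_features taps 1000-wide layers and checks tap names", {
  fx <- tiny_trained_cnn()
  F1 <- extract_features(fx$model, fx$vols, "FC1")
  expect_equal(dim(F1), c(length(fx$vols), 1000L))
  expect_equal(attr(F1, "tap"), "FC1")
  # deterministic forward pass, rows align with input order
  expect_identical(F1, extract_features(fx$model, fx$vols, "FC1"))
  expect_identical(rownames(F1)[1], fx$vols[[1]]$subject_id)

  F2 <- extract_features(fx$model, fx$vols, "FC2")
  F3 <- extract_features(fx$model, fx$vols, "FC3")
  expect_equal(F3[, ], pmax(F1[, ], F2[, ]))
  expect_equal(ncol(F3), 1000L)
  expect_error(extract_features(fx$model, fx$vols, "FC9"), "unknown tap")
})

test_that("the 2000-feature budget holds when stacking FC3 with FC4", {
  fx <- tiny_trained_cnn()
  F3 <- extract_features(fx$model, fx$vols, "FC3")
  spec_r <- build_extractor("resnet15", c(12L, 12L, 12L), base_width = 2L)
  mr <- train_extractor(spec_r, fx$vols, train_config(epochs = 0L, seed = 1L))
  F4 <- extract_features(mr, fx$vols, "FC4")
  expect_equal(dim(F4), c(length(fx$vols), 1000L))
  expect_equal(ncol(cbind(F3, F4)), 2000L)
})

test_that("FC1 features of trained CNN are linearly separable on easy phantoms", {
  fx <- tiny_trained_cnn()
  F1 <- extract_features(fx$model, fx$vols, "FC1")
  # linear probe: ridge least-squares one-vs-all, dual form (n << p)
  Y <- diag(3)[fx$labels + 1L, ]
  Xp <- cbind(1, F1)
  G <- tcrossprod(Xp)
  scores <- G %*% solve(G + 1e-6 * mean(diag(G)) * diag(nrow(Xp)), Y)
  pred <- max.col(scores) - 1L
  expect_gte(mean(pred == fx$labels), 0.95)
})
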