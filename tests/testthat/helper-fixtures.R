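# Locked synthetic-world configurations used across the suite, plus a
# small cache so expensive fixtures (trained extractors) are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Easy phantom world at 28^3: the toy-training configuration (extractor
# sanity checks). Low noise, well-separated nucleus deltas.
easy_phantom_cfg_28 <- function(n = 24L, seed = 42L) {
  phantom_config(n, shape = c(28L, 28L, 28L), noise_sd = 0.05,
                 class_intensity_deltas = c(0, 0.6, 1.2),
                 jitter_voxels = 1L, seed = seed)
}

# Easy phantom world at 16^3: the end-to-end (model 4) configuration.
easy_phantom_cfg_16 <- function(n = 30L, seed = 42L) {
  phantom_config(n, shape = c(16L, 16L, 16L), noise_sd = 0.05,
                 class_intensity_deltas = c(0, 0.6, 1.2),
                 nucleus_radii = c(3L, 3L, 3L), jitter_voxels = 1L,
                 seed = seed)
}

# Locked planted-selection problem for the recovery checks:
# n = 300, N = 100, 10 informative, per-feature offset 0.9, noise columns
# sd 2. See the methods vignette for why these values are the stated world.
locked_planted_problem <- function(seed = 1L) {
  gen_planted_selection(300L, 100L, 10L, effect_size = 0.9, seed = seed,
                        noise_feature_sd = 2)
}

# A tiny trained CNN shared by feature-extraction tests (12^3 phantoms,
# noiseless, so training is fast and features are clean).
tiny_trained_cnn <- function() {
  cache_fixture("tiny_cnn", function() {
    cfg <- phantom_config(18L, shape = c(12L, 12L, 12L), noise_sd = 0,
                          class_intensity_deltas = c(0, 0.6, 1.2),
                          nucleus_radii = c(2L, 2L, 2L),
                          jitter_voxels = 0L, seed = 7L)
    vols <- lapply(gen_volumes(cfg), preprocess_volume,
                   target_shape = c(12L, 12L, 12L))
    spec <- build_extractor("cnn_variant3", c(12L, 12L, 12L), 3L,
                            base_width = 2L)
    model <- train_extractor(spec, vols,
                             train_config(epochs = 12L, batch_size = 6L,
                                          seed = 3L))
    list(model = model, vols = vols,
         labels = vapply(vols, function(v) v$label, integer(1)))
  })
}

# Small planted problem for optimizer contract tests (cheap fitness).
small_planted_problem <- function(seed = 5L) {
  gen_planted_selection(120L, 20L, 4L, effect_size = 1.2, seed = seed,
                        noise_feature_sd = 2)
}
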