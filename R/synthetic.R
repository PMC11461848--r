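#' Phantom generator configuration
#'
#' Describes a population of labeled 3D intensity phantoms that emulate the
#' class structure of subcortical T2 signal change: every volume contains a
#' bright "brain" ellipsoid, and each class modifies a small nucleus-like
#' region (substantia-nigra analogue) by an intensity shift and a radius
#' scale. Classes therefore differ only locally, which forces a volumetric
#' extractor to learn localized features rather than a global intensity cue.
#'
#' @param n_samples number of volumes to generate (must be >= `n_classes`).
#' @param n_classes number of classes; labels are `0 .. n_classes-1` and
#'   balanced to within one sample.
#' @param shape voxel triple (depth, height, width); default 56^3, the input
#'   size consumed by the extractors.
#' @param nucleus_center voxel coordinate of the nucleus (default: volume
#'   centre).
#' @param nucleus_radii voxel triple of base nucleus semi-axes (default:
#'   14% of shape).
#' @param class_intensity_deltas per-class additive intensity shift inside
#'   the nucleus, on top of a common +0.5 nucleus contrast.
#' @param class_radius_scales per-class multiplicative scale of the nucleus
#'   semi-axes.
#' @param noise_sd standard deviation of additive white Gaussian voxel noise.
#' @param jitter_voxels maximum per-axis integer translation of the nucleus
#'   centre, drawn uniformly per sample.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_samples, n_classes = 3L, shape = c(56L, 56L, 56L),
                           nucleus_center = NULL, nucleus_radii = NULL,
                           class_intensity_deltas = NULL,
                           class_radius_scales = NULL,
                           noise_sd = 0.1, jitter_voxels = 1L, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("invalid shape: need a voxel triple with each dim >= 4")
  if (n_samples < n_classes)
    stop("n_samples must be >= n_classes")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (jitter_voxels < 0) stop("jitter_voxels must be >= 0")
  k <- as.integer(n_classes)
  cfg <- list(
    n_samples = as.integer(n_samples), n_classes = k, shape = shape,
    nucleus_center = nucleus_center %||% round(shape / 2),
    nucleus_radii = nucleus_radii %||% pmax(2, round(shape * 0.14)),
    class_intensity_deltas = class_intensity_deltas %||% (0.45 * (seq_len(k) - 1)),
    class_radius_scales = class_radius_scales %||% (1 + 0.12 * (seq_len(k) - 1)),
    noise_sd = noise_sd, jitter_voxels = as.integer(jitter_voxels),
    seed = as.integer(seed))
  if (length(cfg$class_intensity_deltas) != k || length(cfg$class_radius_scales) != k)
    stop("per-class parameter vectors must have length n_classes")
  class(cfg) <- "phantom_config"
  cfg
}

ellipsoid_mask <- function(shape, center, radii) {
  z <- seq_len(shape[1]) - center[1]
  y <- seq_len(shape[2]) - center[2]
  x <- seq_len(shape[3]) - center[3]
  d2 <- outer(outer((z / radii[1])^2, (y / radii[2])^2, `+`),
              (x / radii[3])^2, `+`)
  d2 <= 1
}

#' Generate labeled phantom volumes
#'
#' @param cfg a [phantom_config()].
#' @return list of `volume_sample` objects with balanced integer labels.
#'   Identical configs (including seed) reproduce identical voxels.
#' @export
gen_volumes <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  shape <- cfg$shape
  labels <- rep(seq_len(cfg$n_classes) - 1L, length.out = cfg$n_samples)
  brain <- ellipsoid_mask(shape, round(shape / 2), 0.45 * shape)
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_samples), function(i) {
      lab <- labels[i]
      centre <- cfg$nucleus_center
      if (cfg$jitter_voxels > 0)
        centre <- centre + sample(seq(-cfg$jitter_voxels, cfg$jitter_voxels),
                                  3, replace = TRUE)
      radii <- cfg$nucleus_radii * cfg$class_radius_scales[lab + 1L]
      vox <- array(0, dim = shape)
      vox[brain] <- 1
      nuc <- ellipsoid_mask(shape, centre, radii)
      vox[nuc] <- vox[nuc] + 0.5 + cfg$class_intensity_deltas[lab + 1L]
      if (cfg$noise_sd > 0)
        vox <- vox + array(rnorm(prod(shape), 0, cfg$noise_sd), dim = shape)
      volume_sample(vox, spacing = c(1, 1, 1),
                    subject_id = sprintf("phantom_%03d", i), label = lab,
                    provenance = list(source = "synthetic", format = "phantom"))
    })
  })
}

#' Dual-view latent-factor configuration
#'
#' Two feature views `A = z Lambda_A' + eps_A` and `B = z Lambda_B' + eps_B`
#' share a `d_latent`-dimensional standard-normal latent `z`. The loading
#' matrices have orthogonal columns with norms
#' `s_j = loading_scale / sqrt(j)`, so the population canonical correlations
#' have the closed form `rho_j = s_j^2 / (s_j^2 + noise_sd^2)`.
#'
#' @param n samples; `p`, `q` view dimensions; `d_latent` shared latent
#'   dimension (`<= min(p, q)`).
#' @param p,q view dimensions.
#' @param d_latent shared latent dimension.
#' @param loading_scale scale of the leading loading column.
#' @param noise_sd isotropic noise standard deviation per view.
#' @param seed integer seed.
#' @export
dual_view_config <- function(n, p, q, d_latent, loading_scale = 1,
                             noise_sd = 0.5, seed = 1L) {
  if (d_latent > min(p, q)) stop("d_latent must be <= min(p, q)")
  if (d_latent < 0) stop("d_latent must be >= 0")
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 d_latent = as.integer(d_latent),
                 loading_scale = loading_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "dual_view_config")
}

#' Generate correlated two-view feature matrices
#'
#' @param cfg a [dual_view_config()].
#' @return list with matrices `A` (n x p), `B` (n x q) and
#'   `theoretical_correlations`, the population canonical correlations
#'   (length `min(p, q)`; entries beyond `d_latent` are exactly zero).
#' @export
gen_dual_view_features <- function(cfg) {
  stopifnot(inherits(cfg, "dual_view_config"))
  d <- cfg$d_latent
  with_seed(cfg$seed, {
    s <- if (d > 0) cfg$loading_scale / sqrt(seq_len(d)) else numeric(0)
    La <- if (d > 0) qr.Q(qr(matrix(rnorm(cfg$p * d), cfg$p, d))) %*% diag(s, d)
          else matrix(0, cfg$p, 0)
    Lb <- if (d > 0) qr.Q(qr(matrix(rnorm(cfg$q * d), cfg$q, d))) %*% diag(s, d)
          else matrix(0, cfg$q, 0)
    Z <- matrix(rnorm(cfg$n * max(d, 1)), cfg$n)[, seq_len(d), drop = FALSE]
    A <- Z %*% t(La) + cfg$noise_sd * matrix(rnorm(cfg$n * cfg$p), cfg$n)
    B <- Z %*% t(Lb) + cfg$noise_sd * matrix(rnorm(cfg$n * cfg$q), cfg$n)
    rho <- rep(0, min(cfg$p, cfg$q))
    if (d > 0) {
      r <- if (cfg$noise_sd == 0) rep(1, d) else s^2 / (s^2 + cfg$noise_sd^2)
      rho[seq_len(d)] <- r
    }
    colnames(A) <- sprintf("a%03d", seq_len(cfg$p))
    colnames(B) <- sprintf("b%03d", seq_len(cfg$q))
    list(A = A, B = B, theoretical_correlations = rho)
  })
}

#' Planted feature-selection problem
#'
#' Generates balanced labels and an `n x N` feature matrix in which only a
#' planted subset `S` of `k_informative` columns carries class information.
#' Informative columns are unit-variance Gaussians whose class-conditional
#' means follow a rotating offset pattern (`effect_size * {-1, 0, +1}`
#' cycled across classes), so every informative feature separates one pair
#' of classes with equal strength and the posterior `P(y | x_S)` is exactly
#' a multinomial-logistic rule with linear logits (the classical
#' equal-covariance Gaussian / logistic equivalence). The remaining
#' `N - k` columns are pure label-independent noise with standard
#' deviation `noise_feature_sd` (default 2); the inflated scale makes
#' irrelevant features actively harmful to distance-based wrappers, which
#' is what the feature selector is supposed to exploit.
#' `effect_size = 0` makes every feature uninformative.
#'
#' @param n samples, `N` total features, `k_informative` planted subset size.
#' @param N total number of features.
#' @param k_informative number of informative features (`< N`).
#' @param effect_size per-feature class-mean offset (default 0.9, the locked
#'   configuration used by the recovery tests).
#' @param seed integer seed.
#' @param n_classes number of label groups (default 3); labels balanced to
#'   within one.
#' @param noise_feature_sd standard deviation of the uninformative columns
#'   (default 3).
#' @return object of class `planted_problem` with fields `X`, `y`,
#'   `informative_set`, `effect_size`, `seed`.
#' @export
gen_planted_selection <- function(n, N, k_informative, effect_size = 0.9,
                                  seed = 1L, n_classes = 3L,
                                  noise_feature_sd = 2) {
  if (k_informative >= N) stop("k_informative must be < N")
  if (k_informative < 1) stop("k_informative must be >= 1")
  K <- as.integer(n_classes)
  with_seed(seed, {
    X <- matrix(rnorm(n * N), n, N)
    colnames(X) <- sprintf("f%04d", seq_len(N))
    S <- sort(sample(N, k_informative))
    X[, -S] <- noise_feature_sd * X[, -S, drop = FALSE]
    y <- rep(seq_len(K) - 1L, length.out = n)
    offsets <- seq_len(K) - 2L  # -1, 0, 1 pattern for K = 3
    for (j in seq_len(k_informative))
      X[, S[j]] <- X[, S[j]] + effect_size * offsets[((y + j) %% K) + 1L]
    structure(list(X = X, y = y, informative_set = S,
                   effect_size = effect_size, seed = as.integer(seed),
                   n_classes = K, noise_feature_sd = noise_feature_sd),
              class = "planted_problem")
  })
}

#' Write a feature matrix (and optional labels) to CSV with a header row
#' @param X feature matrix, `y` optional integer labels, `path` output file.
#' @param y optional labels appended as a `label` column.
#' @param path output CSV path.
#' @export
write_feature_csv <- function(X, path, y = NULL) {
  df <- as.data.frame(X)
  if (!is.null(y)) df$label <- as.integer(y)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV written by [write_feature_csv()]
#' @param path CSV path.
#' @return list with `X` (matrix) and `y` (labels or NULL).
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  y <- NULL
  if ("label" %in% names(df)) {
    y <- as.integer(df$label)
    df$label <- NULL
  }
  list(X = as.matrix(df), y = y)
}
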