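#' Fit (regularized) canonical correlation analysis between two views
#'
#' Solves the canonical eigenproblem
#' `S_AA^-1 S_AB S_BB^-1 S_BA w_A = rho^2 w_A` on column-centered views,
#' with each within-view covariance shrunk as
#' `S + lambda * tr(S)/p * I` so the deep-feature regime (p, q >> n) stays
#' well posed. Canonical correlations are the square roots of the
#' eigenvalues; transformation columns are scaled to unit variance of the
#' training variates. Sign convention: the first nonzero loading of each
#' `W_A` column is positive and the `W_B` sign is chosen so every canonical
#' correlation is nonnegative.
#'
#' @param A,B numeric matrices with the same row (sample) count, n >= 3.
#' @param lambda relative shrinkage strength (default 1e-3; 0 = classical
#'   CCA, requires full-rank covariances).
#' @param d number of canonical components to retain; `NULL` keeps every
#'   component with correlation > 1e-6.
#' @param pca_rank optional per-view PCA pre-reduction rank (<= n-1); the
#'   returned `W_A`, `W_B` are composed back to the original feature space.
#' @return object of class `cca_model` with `W_A` (p x d), `W_B` (q x d),
#'   `correlations`, per-view `means`, the training variates and the
#'   regularization record.
#' @export
fit_cca <- function(A, B, lambda = 1e-3, d = NULL, pca_rank = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have the same number of samples")
  n <- nrow(A)
  if (n < 3) stop("need at least 3 samples")
  if (!all(is.finite(A)) || !all(is.finite(B))) stop("non-finite input")
  if (lambda < 0) stop("lambda must be >= 0")
  mean_A <- colMeans(A); mean_B <- colMeans(B)
  Ac <- sweep(A, 2, mean_A); Bc <- sweep(B, 2, mean_B)

  Ra <- NULL; Rb <- NULL
  if (!is.null(pca_rank)) {
    r <- min(pca_rank, n - 1L)
    pa <- svd(Ac, nu = 0, nv = min(r, ncol(Ac)))
    pb <- svd(Bc, nu = 0, nv = min(r, ncol(Bc)))
    Ra <- pa$v; Rb <- pb$v
    Ac <- Ac %*% Ra; Bc <- Bc %*% Rb
  }
  p <- ncol(Ac); q <- ncol(Bc)
  Saa <- crossprod(Ac) / (n - 1)
  Sbb <- crossprod(Bc) / (n - 1)
  Sab <- crossprod(Ac, Bc) / (n - 1)
  if (lambda > 0) {
    diag(Saa) <- diag(Saa) + lambda * sum(diag(Saa)) / p
    diag(Sbb) <- diag(Sbb) + lambda * sum(diag(Sbb)) / q
  }
  M <- solve(Saa, Sab %*% solve(Sbb, t(Sab)))
  eig <- eigen(M)
  keep <- Mod(eig$values) > 0  # descending by modulus already
  vals <- pmin(pmax(Re(eig$values), 0), 1 + 1e-8)
  ord <- order(vals, decreasing = TRUE)
  dmax <- min(p, q, n - 1L)
  d_all <- sum(sqrt(vals) > 1e-6)
  d_use <- if (is.null(d)) min(d_all, dmax) else min(d, dmax, ncol(A), ncol(B))
  if (d_use < 1) d_use <- 1L
  ord <- ord[seq_len(d_use)]

  Wa <- matrix(0, p, d_use); Wb <- matrix(0, q, d_use)
  rho <- numeric(d_use)
  SbbinvSba <- solve(Sbb, t(Sab))
  for (j in seq_len(d_use)) {
    wa <- Re(eig$vectors[, ord[j]])
    wa <- wa / sqrt(drop(crossprod(wa, Saa %*% wa)))
    nz <- which(abs(wa) > 1e-12)[1]
    if (!is.na(nz) && wa[nz] < 0) wa <- -wa
    wb <- SbbinvSba %*% wa
    nb <- sqrt(drop(crossprod(wb, Sbb %*% wb)))
    wb <- if (nb > 1e-300) wb / nb else wb
    r <- drop(crossprod(wa, Sab %*% wb))
    if (r < 0) { wb <- -wb; r <- -r }
    Wa[, j] <- wa; Wb[, j] <- wb; rho[j] <- min(r, 1)
  }
  if (!is.null(Ra)) { Wa <- Ra %*% Wa; Wb <- Rb %*% Wb }

  Astar <- sweep(A, 2, mean_A) %*% Wa
  Bstar <- sweep(B, 2, mean_B) %*% Wb
  structure(list(W_A = Wa, W_B = Wb, correlations = rho,
                 means = list(A = mean_A, B = mean_B),
                 regularization = list(lambda = lambda,
                                       pca_rank = pca_rank),
                 d = d_use, n = n,
                 variates = list(A = Astar, B = Bstar)),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model: d = %d, leading correlations %s>\n", x$d,
              paste(signif(head(x$correlations, 5), 3), collapse = ", ")))
  invisible(x)
}

#' Project two views into fused canonical discriminant features
#'
#' Computes the canonical variates `A* = (A - mean_A) W_A` and
#' `B* = (B - mean_B) W_B` and fuses them either by column-wise
#' concatenation (`Z1_concat`, width `2d`) or by summation (`Z2_sum`,
#' width `d`).
#'
#' @param model a fitted [fit_cca()] model.
#' @param A,B views with the same columns as at fit time.
#' @param mode `"Z1_concat"` or `"Z2_sum"`.
#' @return fused feature matrix with attributes `mode` and `d`.
#' @export
fuse <- function(model, A, B, mode = c("Z1_concat", "Z2_sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "cca_model"))
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != nrow(model$W_A) || ncol(B) != nrow(model$W_B))
    stop("dimension mismatch with fitted model")
  Astar <- sweep(A, 2, model$means$A) %*% model$W_A
  Bstar <- sweep(B, 2, model$means$B) %*% model$W_B
  Z <- if (mode == "Z1_concat") cbind(Astar, Bstar) else Astar + Bstar
  colnames(Z) <- if (mode == "Z1_concat")
    c(sprintf("ccdf_a%03d", seq_len(model$d)),
      sprintf("ccdf_b%03d", seq_len(model$d)))
  else sprintf("ccdf_s%03d", seq_len(model$d))
  attr(Z, "mode") <- mode
  attr(Z, "d") <- model$d
  Z
}

#' Save / load a CCA model as a plain-text archive (CSV matrices + JSON meta)
#' @param model a `cca_model`; `dir` target directory.
#' @param dir archive directory.
#' @export
write_cca_archive <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(model$W_A, file.path(dir, "W_A.csv"), row.names = FALSE)
  write.csv(model$W_B, file.path(dir, "W_B.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(correlations = model$correlations, d = model$d, n = model$n,
         lambda = model$regularization$lambda,
         pca_rank = model$regularization$pca_rank,
         mean_A = model$means$A, mean_B = model$means$B),
    file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}
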