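# Independent oracles, written before/independently of the implementation
# paths they check.

# CCA by whitening + SVD: S_AA^{-1/2} S_AB S_BB^{-1/2} = U D V', canonical
# correlations are the singular values, W_A = S_AA^{-1/2} U.
cca_oracle_svd <- function(A, B, lambda = 0) {
  n <- nrow(A)
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  Saa <- crossprod(Ac) / (n - 1)
  Sbb <- crossprod(Bc) / (n - 1)
  Sab <- crossprod(Ac, Bc) / (n - 1)
  if (lambda > 0) {
    diag(Saa) <- diag(Saa) + lambda * sum(diag(Saa)) / ncol(A)
    diag(Sbb) <- diag(Sbb) + lambda * sum(diag(Sbb)) / ncol(B)
  }
  isqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300))) %*% t(e$vectors)
  }
  Wa <- isqrt(Saa)
  Wb <- isqrt(Sbb)
  sv <- svd(Wa %*% Sab %*% Wb)
  list(cor = sv$d, W_A = Wa %*% sv$u, W_B = Wb %*% sv$v,
       variates_A = Ac %*% Wa %*% sv$u, variates_B = Bc %*% Wb %*% sv$v)
}

# Continuous benchmark objective for the optimizer correctness checks.
sphere_fn <- function(x) sum(x^2)

# Exhaustive optimum of the wrapper fitness over all 2^N masks (tiny N).
exhaustive_best_fitness <- function(X, y, spec) {
  N <- ncol(X)
  best <- Inf
  for (code in 0:(2^N - 1)) {
    mask <- as.integer(intToBits(code)[1:N] == 1)
    f <- evaluate_fitness(mask, X, y, spec)
    if (f < best) best <- f
  }
  best
}

# Reference KNN (pure R) used to cross-check the compiled classifier.
knn_reference <- function(Xtr, ytr, Xte, k, K) {
  apply(Xte, 1, function(x) {
    d <- colSums((t(Xtr) - x)^2)
    nb <- order(d)[seq_len(k)]
    votes <- tabulate(ytr[nb] + 1L, nbins = K)
    which.max(votes) - 1L
  })
}
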