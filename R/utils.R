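# Internal helpers shared across modules.

# Run expr under a local RNG seed, restoring the caller's RNG state.
# Keeps every generator a pure function of its config (no global state).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed fan-out: one master seed yields per-stage/run streams.
# Result stays well below 2^31.
derive_seed <- function(master, offset) {
  as.integer((as.double(master) %% 1000003) * 1009 + 7 * offset) %% 2000000011L
}

# Stratified index split into named fractions (e.g. c(train=.7, val=.15, ...)).
# Remainders are assigned to the first part so every sample lands somewhere.
stratified_split <- function(y, fractions, seed) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  with_seed(seed, {
    parts <- lapply(seq_along(fractions), function(i) integer(0))
    names(parts) <- names(fractions)
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      cuts <- round(cumsum(fractions) * length(idx))
      lo <- c(0L, cuts[-length(cuts)])
      for (i in seq_along(fractions)) {
        take <- if (cuts[i] > lo[i]) idx[(lo[i] + 1L):cuts[i]] else integer(0)
        parts[[i]] <- c(parts[[i]], take)
      }
    }
    parts
  })
}

# Stratified k-fold assignment; returns integer fold id per sample.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Tiny FNV-1a hash of a character scalar; used for config fingerprints.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
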