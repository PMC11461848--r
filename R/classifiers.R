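# Classical classifiers over feature matrices. KNN and the CART trees run
# in compiled code; the SVM is a least-squares SVM (RBF kernel ridge,
# one-vs-rest), the closest available formulation given that no QP/SMO SVM
# library ships in the target environment. Gradient boosting follows the
# multinomial deviance formulation with shallow regression trees.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

argmax_rows <- function(P) max.col(P, ties.method = "first") - 1L

#' Fit a classical classifier
#'
#' @param X numeric feature matrix (n x p).
#' @param y integer class labels `0 .. K-1`.
#' @param method `"knn"`, `"svm"` (least-squares RBF SVM), `"rf"`
#'   (random forest), or `"gb"` (gradient boosting).
#' @param params optional named list: `k` (KNN, default 5); `C`, `gamma`
#'   (SVM, default 10 and `1/(p * mean column variance)`); `ntree`, `mtry`,
#'   `max_depth` (RF, default 100, `sqrt(p)`, 20); `n_stages`, `shrinkage`,
#'   `max_depth` (GB, default 100, 0.1, 3).
#' @param seed integer seed for the tree ensembles.
#' @return object of class `nf_classifier`.
#' @export
classifier_fit <- function(X, y, method = c("gb", "rf", "knn", "svm"),
                           params = list(), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.integer(y)
  K <- max(y) + 1L
  n <- nrow(X); p <- ncol(X)
  fit <- switch(method,
    knn = {
      list(X = X, y = y, k = params$k %||% 5L)
    },
    svm = {
      gamma <- params$gamma %||% {
        v <- mean(apply(X, 2, var))
        if (!is.finite(v) || v < 1e-12) v <- 1
        1 / (p * v)
      }
      C <- params$C %||% 10
      Km <- rbf_kernel(X, X, gamma)
      Tm <- matrix(-1, n, K)
      Tm[cbind(seq_len(n), y + 1L)] <- 1
      alpha <- solve(Km + diag(n) / C, Tm)
      list(X = X, alpha = alpha, gamma = gamma, C = C)
    },
    rf = {
      ntree <- params$ntree %||% 100L
      mtry <- params$mtry %||% max(1L, floor(sqrt(p)))
      max_depth <- params$max_depth %||% 20L
      trees <- with_seed(seed, {
        lapply(seq_len(ntree), function(t) {
          rows <- sample(n, n, replace = TRUE) - 1L
          .tree_grow_cpp(X, as.numeric(y), as.integer(rows), TRUE, K,
                         max_depth, 2L, mtry, derive_seed(seed, t))
        })
      })
      list(trees = trees, K = K)
    },
    gb = {
      M <- params$n_stages %||% 100L
      lr <- params$shrinkage %||% 0.1
      max_depth <- params$max_depth %||% 3L
      Fm <- matrix(0, n, K)
      Yh <- matrix(0, n, K)
      Yh[cbind(seq_len(n), y + 1L)] <- 1
      rows <- as.integer(seq_len(n) - 1L)
      stages <- vector("list", M)
      for (m in seq_len(M)) {
        E <- exp(Fm - apply(Fm, 1, max))
        P <- E / rowSums(E)
        stage <- vector("list", K)
        for (kk in seq_len(K)) {
          r <- Yh[, kk] - P[, kk]
          tr <- .tree_grow_cpp(X, r, rows, FALSE, 1L, max_depth, 5L, p,
                               derive_seed(seed, m * K + kk))
          leaf <- .tree_leaf_cpp(tr, X)
          # Friedman leaf update for multinomial deviance
          gam <- vapply(sort(unique(leaf)), function(id) {
            sel <- leaf == id
            num <- sum(r[sel])
            den <- sum(P[sel, kk] * (1 - P[sel, kk]))
            (K - 1) / K * if (den > 1e-12) num / den else 0
          }, 0)
          names(gam) <- as.character(sort(unique(leaf)))
          Fm[, kk] <- Fm[, kk] + lr * gam[as.character(leaf)]
          stage[[kk]] <- list(tree = tr, gamma = gam)
        }
        stages[[m]] <- stage
      }
      list(stages = stages, K = K, shrinkage = lr)
    })
  structure(list(method = method, fit = fit, K = K, p = p, seed = seed),
            class = "nf_classifier")
}

#' Predict class labels from a fitted classifier
#' @param object an `nf_classifier`; `newdata` feature matrix.
#' @param newdata feature matrix with the training column count.
#' @param ... unused.
#' @return integer labels `0 .. K-1`.
#' @export
predict.nf_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("feature count mismatch")
  f <- object$fit
  switch(object$method,
    knn = .knn_predict_cpp(f$X, f$y, X, as.integer(seq_len(ncol(X)) - 1L),
                           f$k, object$K),
    svm = argmax_rows(rbf_kernel(X, f$X, f$gamma) %*% f$alpha),
    rf = {
      P <- matrix(0, nrow(X), object$K)
      for (tr in f$trees) {
        leaf <- .tree_leaf_cpp(tr, X)
        P <- P + tr$value[leaf + 1L, , drop = FALSE]
      }
      argmax_rows(P)
    },
    gb = {
      Fm <- matrix(0, nrow(X), object$K)
      for (stage in f$stages)
        for (kk in seq_len(object$K)) {
          s <- stage[[kk]]
          leaf <- .tree_leaf_cpp(s$tree, X)
          Fm[, kk] <- Fm[, kk] + f$shrinkage * s$gamma[as.character(leaf)]
        }
      argmax_rows(Fm)
    })
}
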