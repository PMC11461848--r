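#' Classification metrics (accuracy, precision, recall, F1)
#'
#' Computes the confusion matrix and the four headline metrics. Precision,
#' recall and F1 are averaged over classes, unweighted (`macro`, default)
#' or weighted by class support. A class that is never predicted gets
#' precision 0 (with a warning); a class absent from the truth gets
#' recall 0.
#'
#' @param y_true,y_pred equal-length integer label vectors.
#' @param n_classes number of classes (default: inferred).
#' @param average `"macro"` or `"weighted"`.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `per_class`
#'   and `confusion` (rows = truth).
#' @export
compute_metrics <- function(y_true, y_pred, n_classes = NULL,
                            average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty label vectors")
  K <- n_classes %||% (max(c(y_true, y_pred)) + 1L)
  lv <- seq_len(K) - 1L
  conf <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  conf <- matrix(as.numeric(conf), K, K,
                 dimnames = list(truth = lv, pred = lv))
  tp <- diag(conf)
  pred_tot <- colSums(conf)
  true_tot <- rowSums(conf)
  if (any(pred_tot == 0 & true_tot > 0))
    warning("class never predicted; its precision set to 0")
  prec <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  rec <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- if (average == "macro") rep(1 / K, K) else true_tot / sum(true_tot)
  list(accuracy = sum(tp) / length(y_true),
       precision = sum(wts * prec), recall = sum(wts * rec),
       f1 = sum(wts * f1),
       per_class = data.frame(class = lv, precision = prec, recall = rec,
                              f1 = f1, support = true_tot),
       confusion = conf)
}

#' Stratified k-fold cross-validated evaluation
#'
#' @param X feature matrix; `y` integer labels `0 .. K-1`.
#' @param y integer labels.
#' @param classifier classifier name for [classifier_fit()].
#' @param k number of folds (>= 2); classes smaller than `k` degrade to
#'   fewer effective folds with a warning.
#' @param seed fold-assignment and classifier seed.
#' @param params classifier hyperparameters.
#' @param average metric averaging, `"macro"` (default) or `"weighted"`.
#' @return object of class `evaluation_report`: per-fold and mean metrics
#'   plus the fold-summed confusion matrix.
#' @export
kfold_evaluate <- function(X, y, classifier = "gb", k = 5L, seed = 1L,
                           params = list(), average = "macro") {
  X <- as.matrix(X); y <- as.integer(y)
  if (k < 2L) stop("k must be >= 2")
  if (length(unique(y)) < 2L) stop("single-class labels")
  if (min(table(y)) < k)
    warning("some class has fewer members than k; folds degrade gracefully")
  K <- max(y) + 1L
  folds <- stratified_folds(y, k, seed)
  per_fold <- list()
  conf_sum <- matrix(0, K, K)
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    model <- classifier_fit(X[tr, , drop = FALSE], y[tr], classifier,
                            params = params, seed = derive_seed(seed, f))
    pred <- predict(model, X[te, , drop = FALSE])
    m <- suppressWarnings(compute_metrics(y[te], pred, n_classes = K,
                                          average = average))
    conf_sum <- conf_sum + m$confusion
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, f1 = m$f1)
  }
  per_fold <- do.call(rbind, per_fold)
  dimnames(conf_sum) <- list(truth = seq_len(K) - 1L, pred = seq_len(K) - 1L)
  structure(list(classifier = classifier, k_folds = as.integer(k),
                 per_fold = per_fold,
                 mean = colMeans(per_fold[, -1, drop = FALSE]),
                 confusion = conf_sum, seed = as.integer(seed),
                 params = params, average = average),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report %s, %d-fold: acc %.3f prec %.3f rec %.3f f1 %.3f>\n",
              x$classifier, x$k_folds, x$mean[["accuracy"]],
              x$mean[["precision"]], x$mean[["recall"]], x$mean[["f1"]]))
  invisible(x)
}

#' Export an evaluation report as JSON
#' @param x an `evaluation_report`; `path` output file.
#' @param path output JSON file.
#' @export
write_evaluation_json <- function(x, path) {
  jsonlite::write_json(
    list(classifier = x$classifier, k_folds = x$k_folds,
         mean = as.list(x$mean), per_fold = x$per_fold,
         confusion = x$confusion, seed = x$seed, average = x$average),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
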