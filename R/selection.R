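#' Optimizer configuration for wrapper feature selection
#'
#' Defaults follow the study's search settings: population 100, 200
#' iterations, search box `[0, 1]`, binarization threshold 0.5, 20
#' independent runs, and the published per-algorithm parameters
#' (WOA `b = 1`; PSO `c1 = c2 = 2`, `w = 0.9`; GSA `G0 = 100`,
#' `alpha = 20`; GA `CR = 0.8`, `MR = 0.01`, tournament size 3;
#' ACO `tau = 1`, `eta = 1`, `alpha = 1`, `beta = 0.1`, `rho = 0.2`).
#'
#' @param algorithm one of `woa`, `pso`, `ga`, `gsa`, `aco`.
#' @param population agents per iteration (>= 2).
#' @param iterations iterations per run (>= 1).
#' @param lower,upper continuous search bounds.
#' @param independent_runs restarts with derived seeds.
#' @param threshold binarization threshold in (0, 1); positions >=
#'   threshold select the feature.
#' @param params named list overriding algorithm-specific parameters.
#' @param seed master seed; run r uses a seed derived from it.
#' @export
optimizer_config <- function(algorithm = c("woa", "pso", "ga", "gsa", "aco"),
                             population = 100L, iterations = 200L,
                             lower = 0, upper = 1, independent_runs = 20L,
                             threshold = 0.5, params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (population < 2L) stop("population must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (lower >= upper) stop("bounds must satisfy lower < upper")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  defaults <- switch(algorithm,
    woa = list(b = 1),
    pso = list(c1 = 2, c2 = 2, w = 0.9),
    gsa = list(G0 = 100, alpha = 20),
    ga = list(cr = 0.8, mr = 0.01, ts = 3L),
    aco = list(tau = 1, eta = 1, alpha = 1, beta = 0.1, rho = 0.2))
  structure(list(algorithm = algorithm, population = as.integer(population),
                 iterations = as.integer(iterations), lower = lower,
                 upper = upper, independent_runs = as.integer(independent_runs),
                 threshold = threshold,
                 params = modifyList(defaults, params), seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Fitness specification for wrapper selection
#'
#' The fitness of a mask R over N features is
#' `f = alpha * err + (1 - alpha) * |R| / N`, where `err` is the KNN error
#' rate on the selected columns. With `cv_folds > 1` (default 5) the error
#' is the stratified k-fold cross-validation error over the selection data,
#' with one fixed, seeded fold assignment per optimizer run; with
#' `cv_folds = 1` it is the validation error of a single fixed stratified
#' train/validation split. Either way the landscape is deterministic
#' within a run. Lower is better; the empty mask scores 1.0 by convention.
#'
#' @param alpha weight on the classification error (default 0.99; the
#'   subset-size weight is `beta = 1 - alpha`).
#' @param knn_k neighbors in the fitness classifier (default 5).
#' @param cv_folds folds of the internal error estimate (default 5; 1 =
#'   single held-out split).
#' @param train_fraction stratified train share when `cv_folds = 1`.
#' @param seed fold/split seed (overridden per run by the selectors).
#' @export
fitness_spec <- function(alpha = 0.99, knn_k = 5L, cv_folds = 5L,
                         train_fraction = 0.8, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (cv_folds < 1) stop("cv_folds must be >= 1")
  structure(list(alpha = alpha, beta = 1 - alpha, knn_k = as.integer(knn_k),
                 cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 split_idx = NULL),
            class = "fitness_spec")
}

fitness_split <- function(y, spec) {
  parts <- stratified_split(y, c(train = spec$train_fraction,
                                 val = 1 - spec$train_fraction),
                            seed = spec$seed)
  if (length(parts$val) == 0) parts$val <- parts$train
  parts
}

#' Binarize a continuous search position into a feature mask
#' @param position numeric vector in the search box.
#' @param threshold selection threshold; `position >= threshold` maps to 1
#'   (ties select the feature).
#' @return integer 0/1 mask.
#' @export
binarize <- function(position, threshold = 0.5) {
  as.integer(position >= threshold)
}

#' Evaluate the wrapper-selection fitness of a binary mask
#' @param mask 0/1 vector, one entry per feature column.
#' @param X feature matrix; `y` integer labels.
#' @param y integer labels.
#' @param spec a [fitness_spec()].
#' @return scalar fitness (lower is better); empty masks return 1.0.
#' @export
evaluate_fitness <- function(mask, X, y, spec) {
  if (length(mask) != ncol(X)) stop("mask length must equal feature count")
  if (length(unique(y)) < 2L) stop("labels must contain >= 2 classes")
  R <- sum(mask != 0)
  if (R == 0L) return(1.0)
  cols <- which(mask != 0) - 1L
  K <- max(y) + 1L
  cvk <- spec$cv_folds %||% 5L
  if (cvk > 1L) {
    folds <- spec$fold_id %||% stratified_folds(y, cvk, spec$seed)
    nerr <- .knn_cv_errors_cpp(X, as.integer(y), as.integer(folds), cols,
                               spec$knn_k, K)
    err <- nerr / length(y)
  } else if (!is.null(spec$cache)) { # pre-split matrices (optimizer hot path)
    cc <- spec$cache
    pred <- .knn_predict_cpp(cc$Xtr, cc$ytr, cc$Xval, cols, spec$knn_k, cc$K)
    err <- mean(pred != cc$yval)
  } else {
    split <- spec$split_idx %||% fitness_split(y, spec)
    pred <- .knn_predict_cpp(X[split$train, , drop = FALSE],
                             as.integer(y[split$train]),
                             X[split$val, , drop = FALSE],
                             as.integer(cols), spec$knn_k, K)
    err <- mean(pred != y[split$val])
  }
  spec$alpha * err + spec$beta * R / length(mask)
}

run_selection <- function(X, y, cfg, spec) {
  N <- ncol(X)
  binary_native <- cfg$algorithm %in% c("ga", "aco")
  runs <- vector("list", cfg$independent_runs)
  t0 <- proc.time()[["elapsed"]]
  for (r in seq_len(cfg$independent_runs)) {
    run_seed <- derive_seed(cfg$seed, 100L + r)
    spec_r <- spec
    spec_r$seed <- derive_seed(cfg$seed, 500L + r)
    if ((spec$cv_folds %||% 5L) > 1L) {
      spec_r$fold_id <- stratified_folds(y, spec$cv_folds, spec_r$seed)
    } else {
      spec_r$split_idx <- fitness_split(y, spec_r)
      spec_r$cache <- list(
        Xtr = X[spec_r$split_idx$train, , drop = FALSE],
        ytr = as.integer(y[spec_r$split_idx$train]),
        Xval = X[spec_r$split_idx$val, , drop = FALSE],
        yval = as.integer(y[spec_r$split_idx$val]),
        K = max(y) + 1L)
    }
    fn <- if (binary_native) {
      function(bits) evaluate_fitness(bits, X, y, spec_r)
    } else {
      function(pos) evaluate_fitness(binarize(pos, cfg$threshold), X, y, spec_r)
    }
    pr <- cfg$params
    res <- switch(cfg$algorithm,
      woa = woa_optimize(fn, N, cfg$population, cfg$iterations, cfg$lower,
                         cfg$upper, b = pr$b, seed = run_seed),
      pso = pso_optimize(fn, N, cfg$population, cfg$iterations, cfg$lower,
                         cfg$upper, c1 = pr$c1, c2 = pr$c2, w = pr$w,
                         seed = run_seed),
      gsa = gsa_optimize(fn, N, cfg$population, cfg$iterations, cfg$lower,
                         cfg$upper, G0 = pr$G0, alpha = pr$alpha,
                         seed = run_seed),
      ga = ga_optimize(fn, N, cfg$population, cfg$iterations, cr = pr$cr,
                       mr = pr$mr, ts = pr$ts, seed = run_seed),
      aco = aco_optimize(fn, N, cfg$population, cfg$iterations, tau = pr$tau,
                         eta = pr$eta, alpha = pr$alpha, beta = pr$beta,
                         rho = pr$rho, seed = run_seed),
      stop("unknown algorithm: ", cfg$algorithm))
    mask <- if (binary_native) as.integer(res$best_position)
            else binarize(res$best_position, cfg$threshold)
    runs[[r]] <- list(mask = mask, fitness = res$best_fitness,
                      curve = res$curve, seed = run_seed,
                      selection_size = sum(mask))
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  bi <- which.min(vapply(runs, `[[`, 0, "fitness"))
  best <- runs[[bi]]
  structure(list(algorithm = cfg$algorithm, mask = best$mask,
                 fitness = best$fitness, selection_size = best$selection_size,
                 convergence = best$curve,
                 runs = runs, best_run = bi, elapsed = elapsed,
                 config = cfg, fitness_spec = spec),
            class = "selection_result")
}

#' Whale-optimization wrapper feature selection
#'
#' Runs WOA over `[lower, upper]^N`, binarizes each agent position at the
#' configured threshold, scores masks with [evaluate_fitness()], and
#' repeats for `independent_runs` restarts with derived seeds. The best
#' mask across runs is returned together with every run's convergence
#' curve.
#'
#' @param X feature matrix; `y` integer labels.
#' @param y integer labels (0-based classes).
#' @param cfg an [optimizer_config()] with `algorithm = "woa"`.
#' @param spec a [fitness_spec()].
#' @return object of class `selection_result`.
#' @export
woa_select <- function(X, y, cfg = optimizer_config("woa"),
                       spec = fitness_spec()) {
  if (cfg$algorithm != "woa") stop("cfg$algorithm must be 'woa'")
  run_selection(X, y, cfg, spec)
}

#' Baseline metaheuristic feature selection (PSO / GA / GSA / ACO)
#'
#' Same fitness, binarization, bounds and run budget as [woa_select()];
#' GA and ACO operate natively on bit strings.
#'
#' @inheritParams woa_select
#' @export
baseline_select <- function(X, y, cfg, spec = fitness_spec()) {
  if (!cfg$algorithm %in% c("pso", "ga", "gsa", "aco"))
    stop("unknown algorithm: ", cfg$algorithm,
         " (baselines: pso, ga, gsa, aco)")
  run_selection(X, y, cfg, spec)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result %s: fitness %.5f, |R| = %d of %d, %d runs>\n",
              x$algorithm, x$fitness, x$selection_size, length(x$mask),
              length(x$runs)))
  invisible(x)
}

#' Compare optimizers on one selection problem
#'
#' Runs each algorithm under the identical fitness, bounds and budget and
#' tabulates mean/best fitness over runs, mean selection size, downstream
#' KNN validation accuracy of the best mask, and elapsed time; the
#' per-iteration mean convergence curves are returned for plotting.
#'
#' @param X feature matrix; `y` labels.
#' @param y integer labels.
#' @param algorithms character vector of algorithm names.
#' @param cfg an [optimizer_config()] (its `algorithm` field is overridden).
#' @param spec a [fitness_spec()].
#' @return list with `table` (one row per algorithm) and `curves`.
#' @export
compare_optimizers <- function(X, y, algorithms = c("woa", "pso", "ga",
                                                    "gsa", "aco"),
                               cfg = optimizer_config(), spec = fitness_spec()) {
  if (length(algorithms) < 1) stop("need at least one algorithm")
  results <- lapply(algorithms, function(alg) {
    cfg_a <- optimizer_config(alg, cfg$population, cfg$iterations, cfg$lower,
                              cfg$upper, cfg$independent_runs, cfg$threshold,
                              seed = cfg$seed)
    run_selection(X, y, cfg_a, spec)
  })
  names(results) <- algorithms
  acc_spec <- spec
  acc_spec$split_idx <- fitness_split(y, spec)
  tab <- do.call(rbind, lapply(algorithms, function(alg) {
    r <- results[[alg]]
    fits <- vapply(r$runs, `[[`, 0, "fitness")
    sizes <- vapply(r$runs, `[[`, 0, "selection_size")
    cols <- which(r$mask != 0) - 1L
    acc <- if (length(cols) == 0) 1 / length(unique(y)) else {
      K <- max(y) + 1L
      pred <- .knn_predict_cpp(X[acc_spec$split_idx$train, , drop = FALSE],
                               as.integer(y[acc_spec$split_idx$train]),
                               X[acc_spec$split_idx$val, , drop = FALSE],
                               as.integer(cols), spec$knn_k, K)
      mean(pred == y[acc_spec$split_idx$val])
    }
    data.frame(algorithm = alg, accuracy = acc, mean_fitness = mean(fits),
               best_fitness = min(fits), mean_selection_size = mean(sizes),
               time = r$elapsed)
  }))
  curves <- lapply(results, function(r) {
    rowMeans(vapply(r$runs, `[[`, numeric(cfg$iterations), "curve"))
  })
  list(table = tab, curves = curves, results = results)
}

#' Export a selection result as JSON (mask, indices, config echo, seeds)
#' @param x a `selection_result`; `path` output JSON file.
#' @param path output JSON file.
#' @export
write_selection_json <- function(x, path) {
  jsonlite::write_json(
    list(algorithm = x$algorithm, fitness = x$fitness,
         selection_size = x$selection_size, mask = x$mask,
         selected_indices = which(x$mask != 0),
         convergence = x$convergence,
         run_seeds = vapply(x$runs, `[[`, 0L, "seed"),
         config = list(population = x$config$population,
                       iterations = x$config$iterations,
                       lower = x$config$lower, upper = x$config$upper,
                       threshold = x$config$threshold,
                       independent_runs = x$config$independent_runs,
                       params = x$config$params, seed = x$config$seed),
         alpha = x$fitness_spec$alpha, knn_k = x$fitness_spec$knn_k),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
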