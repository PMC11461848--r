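#' Pipeline configuration
#'
#' One config drives the four model variants: `model1` (CNN FC3 features
#' into a classical classifier), `model2` (residual-network FC4 features),
#' `model3` (CCA fusion of FC3 and FC4, no selection) and `model4` (fusion
#' followed by whale-optimization feature selection). Exactly one data
#' source is used: a synthetic phantom config, a directory of
#' NIfTI/DICOM volumes with a label manifest CSV (`file,label` columns),
#' or two precomputed feature CSVs (skips extractor training).
#'
#' @param model one of `model1`..`model4`.
#' @param data list describing the source: `list(type = "synthetic",
#'   phantom = phantom_config(...))`, `list(type = "volumes", dir = ...,
#'   labels = ...)`, or `list(type = "features", view_a = ..., view_b = ...)`
#'   (CSV paths written by [write_feature_csv()]).
#' @param base_width extractor filter width (see [build_extractor()]).
#' @param cnn_train,resnet_train [train_config()]s for the two extractors.
#' @param fusion list of CCA settings: `lambda`, `d`, `pca_rank`, `mode`
#'   (`"Z1_concat"` default or `"Z2_sum"`).
#' @param selection an [optimizer_config()] (model4 only).
#' @param fitness a [fitness_spec()] (model4 only).
#' @param classifier,k_folds,classifier_params final evaluation settings.
#' @param out_dir artifact directory or `NULL` for no persistence.
#' @param seed master seed; every stage derives its own stream from it.
#' @export
pipeline_config <- function(model = c("model4", "model1", "model2", "model3"),
                            data = list(type = "synthetic",
                                        phantom = phantom_config(30L)),
                            base_width = 32L,
                            cnn_train = train_config(),
                            resnet_train = train_config(),
                            fusion = list(lambda = 1e-3, d = NULL,
                                          pca_rank = NULL, mode = "Z1_concat"),
                            selection = optimizer_config("woa"),
                            fitness = fitness_spec(),
                            classifier = "gb", k_folds = 5L,
                            classifier_params = list(),
                            out_dir = NULL, seed = 1L) {
  model <- match.arg(model)
  if (!is.list(data) || is.null(data$type) ||
      !data$type %in% c("synthetic", "volumes", "features"))
    stop("invalid config: data$type must be synthetic, volumes or features")
  structure(list(model = model, data = data, base_width = as.integer(base_width),
                 cnn_train = cnn_train, resnet_train = resnet_train,
                 fusion = modifyList(list(lambda = 1e-3, d = NULL,
                                          pca_rank = NULL,
                                          mode = "Z1_concat"), fusion),
                 selection = selection, fitness = fitness,
                 classifier = classifier, k_folds = as.integer(k_folds),
                 classifier_params = classifier_params,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage=%s elapsed=%.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full classification pipeline
#'
#' Executes only the stages the chosen model requires, persists every
#' intermediate artifact (feature CSVs, CCA archive, selection JSON,
#' evaluation JSON) plus a seed/config manifest when `out_dir` is set, and
#' is fully reproducible from the master seed.
#'
#' @param cfg a [pipeline_config()].
#' @return list with the final `evaluation` report, the feature matrix
#'   actually classified, and (model-dependent) the `cca` model and
#'   `selection` result, plus the run `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    invisible(NULL)
  }
  seeds <- list(data = derive_seed(cfg$seed, 11L),
                cnn = derive_seed(cfg$seed, 12L),
                resnet = derive_seed(cfg$seed, 13L),
                selection = derive_seed(cfg$seed, 14L),
                evaluation = derive_seed(cfg$seed, 15L))
  artifacts <- list()
  need_cnn <- cfg$model %in% c("model1", "model3", "model4")
  need_res <- cfg$model %in% c("model2", "model3", "model4")

  feats <- list(A = NULL, B = NULL)
  y <- NULL
  if (cfg$data$type == "features") {
    got <- run_stage("load_features", log, {
      a <- read_feature_csv(cfg$data$view_a)
      b <- if (!is.null(cfg$data$view_b)) read_feature_csv(cfg$data$view_b)
      list(a = a, b = b)
    })
    feats$A <- got$a$X; y <- got$a$y
    if (!is.null(got$b)) feats$B <- got$b$X
    input_shape <- NULL
  } else {
    vols <- run_stage("data", log, {
      if (cfg$data$type == "synthetic") {
        ph <- cfg$data$phantom
        ph$seed <- seeds$data
        gen_volumes(ph)
      } else {
        man <- read.csv(cfg$data$labels)
        lapply(seq_len(nrow(man)), function(i)
          read_volume(file.path(cfg$data$dir, man$file[i]),
                      label = man$label[i]))
      }
    })
    input_shape <- if (cfg$data$type == "synthetic") cfg$data$phantom$shape
                   else c(56L, 56L, 56L)
    vols <- run_stage("preprocess", log,
                      lapply(vols, preprocess_volume,
                             target_shape = input_shape))
    y <- vapply(vols, function(v) v$label, integer(1))
    n_classes <- length(unique(y))
    if (need_cnn) {
      spec <- build_extractor("cnn_variant3", input_shape, n_classes,
                              cfg$base_width)
      tcfg <- cfg$cnn_train; tcfg$seed <- seeds$cnn
      cnn <- run_stage("train_cnn", log, train_extractor(spec, vols, tcfg))
      feats$A <- run_stage("extract_cnn", log,
                           extract_features(cnn, vols, "FC3"))
      if (!is.null(out)) {
        write_feature_csv(feats$A, file.path(out, "features_cnn_fc3.csv"), y)
        artifacts$features_cnn <- "features_cnn_fc3.csv"
        if (nrow(cnn$history) > 0)
          write.csv(cnn$history, file.path(out, "history_cnn.csv"),
                    row.names = FALSE)
      }
    }
    if (need_res) {
      spec <- build_extractor("resnet15", input_shape, n_classes,
                              cfg$base_width)
      tcfg <- cfg$resnet_train; tcfg$seed <- seeds$resnet
      res <- run_stage("train_resnet", log, train_extractor(spec, vols, tcfg))
      feats$B <- run_stage("extract_resnet", log,
                           extract_features(res, vols, "FC4"))
      if (!is.null(out)) {
        write_feature_csv(feats$B, file.path(out, "features_resnet_fc4.csv"), y)
        artifacts$features_resnet <- "features_resnet_fc4.csv"
      }
    }
  }

  cca <- NULL; sel <- NULL
  X_final <- switch(cfg$model, model1 = feats$A, model2 = feats$B %||% feats$A,
                    feats$A)
  if (cfg$model %in% c("model3", "model4")) {
    if (is.null(feats$B)) stop("stage 'fuse' failed: second view missing")
    cca <- run_stage("fuse", log,
                     fit_cca(feats$A, feats$B, lambda = cfg$fusion$lambda,
                             d = cfg$fusion$d, pca_rank = cfg$fusion$pca_rank))
    X_final <- fuse(cca, feats$A, feats$B, cfg$fusion$mode)
    if (!is.null(out)) {
      write_cca_archive(cca, file.path(out, "cca_model"))
      write_feature_csv(X_final, file.path(out, "features_fused.csv"), y)
      artifacts$cca <- "cca_model"
      artifacts$fused <- "features_fused.csv"
    }
  }
  if (cfg$model == "model4") {
    scfg <- cfg$selection; scfg$seed <- seeds$selection
    sel <- run_stage("select", log,
                     woa_select(X_final, y, scfg, cfg$fitness))
    X_final <- X_final[, sel$mask != 0, drop = FALSE]
    if (!is.null(out)) {
      write_selection_json(sel, file.path(out, "selection.json"))
      artifacts$selection <- "selection.json"
    }
  }

  evaluation <- run_stage("evaluate", log,
                          kfold_evaluate(X_final, y, cfg$classifier,
                                         cfg$k_folds, seeds$evaluation,
                                         cfg$classifier_params))
  manifest <- list(model = cfg$model, seed = cfg$seed, seeds = seeds,
                   config_hash = fnv1a(paste(deparse(cfg), collapse = "")),
                   n_samples = length(y),
                   n_features_final = ncol(X_final),
                   selection_size = if (!is.null(sel)) sel$selection_size,
                   mean_accuracy = evaluation$mean[["accuracy"]],
                   artifacts = artifacts)
  if (!is.null(out)) {
    write_evaluation_json(evaluation, file.path(out, "evaluation.json"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("run at %s", format(Sys.time())), log_lines),
               file.path(out, "run.log"))
  }
  list(model = cfg$model, evaluation = evaluation, features = X_final,
       labels = y, cca = cca, selection = sel, manifest = manifest)
}
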