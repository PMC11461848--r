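#' Training configuration for an extractor
#'
#' Defaults follow the study protocol: 30 epochs, Adam, L2 weight decay
#' 1e-4, a 70/15/15 train/validation/test split, early stopping on
#' validation loss (patience 5), and a learning rate of 1e-3 for the CNN or
#' 1e-4 for the residual network (applied automatically when
#' `learning_rate` is `NULL`).
#'
#' @param learning_rate step size; `NULL` picks the architecture default.
#' @param epochs training epochs (default 30).
#' @param weight_decay L2 penalty on convolution/dense weights.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param batch_size minibatch size (default 64).
#' @param split train/validation/test fractions summing to 1.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param seed integer seed controlling split, init and batch order.
#' @export
train_config <- function(learning_rate = NULL, epochs = 30L,
                         weight_decay = 1e-4, optimizer = c("adam", "sgd"),
                         batch_size = 64L, split = c(0.70, 0.15, 0.15),
                         early_stopping_patience = 5L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (!is.null(learning_rate) && learning_rate <= 0)
    stop("learning_rate must be > 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay, optimizer = optimizer,
                 batch_size = as.integer(batch_size), split = split,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

default_lr <- function(kind) if (kind == "resnet15") 1e-4 else 1e-3

# He-normal init for conv/dense weights, zeros for biases, (1, 0) for BN.
# The closing batch-norm gain of every residual unit starts at 0.1 so each
# unit begins near-identity; deep residual stacks otherwise blow up the
# forward signal and saturate the softmax at init. (Not exactly 0: the
# following ReLU would then block the gain's own gradient forever.)
init_extractor_params <- function(spec, seed) {
  params <- numeric(spec$n_params)
  zero_bn <- integer(0)
  for (i in seq_along(spec$layers))
    if (spec$layers[[i]]$kind_name == "res_add" && i >= 3 &&
        spec$layers[[i - 2]]$kind_name == "batchnorm")
      zero_bn <- c(zero_bn, spec$layers[[i - 2]]$poff)
  with_seed(seed, {
    for (l in spec$layers) {
      if (l$pcnt == 0) next
      idx <- seq(l$poff + 1, l$poff + l$pcnt)
      if (l$kind_name == "conv") {
        nw <- 27 * l$c_in * l$c_out
        fan_in <- 27 * l$c_in
        params[idx[seq_len(nw)]] <- rnorm(nw, 0, sqrt(2 / fan_in))
      } else if (l$kind_name == "dense") {
        nw <- l$c_in * l$c_out
        params[idx[seq_len(nw)]] <- rnorm(nw, 0, sqrt(2 / l$c_in))
      } else if (l$kind_name == "batchnorm") {
        params[idx[seq_len(l$c_out)]] <- if (l$poff %in% zero_bn) 0.1 else 1
      } else if (l$kind_name == "res_add") {
        c_save <- l$pcnt / l$c_out
        params[idx] <- rnorm(l$pcnt, 0, sqrt(2 / c_save))
      }
    }
  })
  params
}

# 1 on entries that receive L2 decay (conv/dense/projection weights only).
weight_decay_mask <- function(spec) {
  m <- numeric(spec$n_params)
  for (l in spec$layers) {
    if (l$pcnt == 0) next
    nw <- switch(l$kind_name,
                 conv = 27 * l$c_in * l$c_out,
                 dense = l$c_in * l$c_out,
                 res_add = l$pcnt,
                 0)
    if (nw > 0) m[seq(l$poff + 1, l$poff + nw)] <- 1
  }
  m
}

init_bn_state <- function(spec) {
  lapply(Filter(function(l) l$kind_name == "batchnorm", spec$layers),
         function(l) list(mean = numeric(l$c_out), var = rep(1, l$c_out)))
}

# Stack volumes into the (n * nvox) x 1 input matrix the engine expects.
volumes_to_input <- function(vols) {
  matrix(unlist(lapply(vols, function(v) as.numeric(v$voxels))), ncol = 1)
}

check_volumes <- function(data, spec) {
  if (length(data) == 0) stop("empty data")
  for (v in data) {
    if (!inherits(v, "volume_sample")) stop("data must be volume_sample objects")
    if (!all(dim(v$voxels) == spec$input_shape))
      stop("volume shape ", paste(dim(v$voxels), collapse = "x"),
           " does not match spec input ",
           paste(spec$input_shape, collapse = "x"),
           "; run preprocess_volume() first")
  }
  vapply(data, function(v) v$label, integer(1))
}

eval_net <- function(spec, params, bn_state, vols, y = NULL) {
  X <- volumes_to_input(vols)
  r <- .nn_batch_cpp(params, spec$layers, X, length(vols), integer(0),
                     bn_state, FALSE, 1L, 0L)
  probs <- r$probs
  out <- list(probs = probs, pred = max.col(probs, ties.method = "first") - 1L)
  if (!is.null(y)) {
    out$loss <- -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)))
    out$acc <- mean(out$pred == y)
  }
  out
}

#' Train a volumetric feature extractor
#'
#' Minibatch training with softmax cross-entropy. The data are split
#' stratified train/validation/test per `cfg$split`; per-epoch train and
#' validation loss/accuracy are recorded, early stopping monitors
#' validation loss, and the returned model carries the best-validation
#' checkpoint (parameters and batch-norm running statistics).
#'
#' @param spec a [build_extractor()] manifest.
#' @param data list of preprocessed `volume_sample`s with labels.
#' @param cfg a [train_config()].
#' @return object of class `extractor_model` with `params`, `bn_state`,
#'   `history` (one row per epoch) and the split indices.
#' @export
train_extractor <- function(spec, data, cfg = train_config()) {
  stopifnot(inherits(spec, "network_spec"))
  y <- check_volumes(data, spec)
  if (any(is.na(y))) stop("all training volumes need labels")
  if (length(unique(y)) < 2L) stop("single-class data: need >= 2 classes")
  lr <- cfg$learning_rate %||% default_lr(spec$kind)
  n <- length(data)

  parts <- stratified_split(y, c(train = cfg$split[1], val = cfg$split[2],
                                 test = cfg$split[3]),
                            seed = derive_seed(cfg$seed, 1L))
  tr <- sort(parts$train); va <- sort(parts$val); te <- sort(parts$test)
  if (length(tr) == 0) tr <- seq_len(n)
  use_val <- length(va) > 0

  params <- init_extractor_params(spec, derive_seed(cfg$seed, 2L))
  bn_state <- init_bn_state(spec)
  wd_mask <- weight_decay_mask(spec)
  hist <- list()

  model <- structure(list(spec = spec, params = params, bn_state = bn_state,
                          history = data.frame(), split = parts,
                          config = cfg, trained = FALSE),
                     class = "extractor_model")
  if (cfg$epochs == 0L) return(model)

  m1 <- numeric(length(params)); v2 <- numeric(length(params)); tstep <- 0
  best <- list(loss = Inf, params = params, bn = bn_state, epoch = 0L)
  patience_left <- cfg$early_stopping_patience
  nvox <- prod(spec$input_shape)
  vols_tr <- data[tr]; y_tr <- y[tr]

  with_seed(derive_seed(cfg$seed, 3L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(tr))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (b in batches) {
        X <- volumes_to_input(vols_tr[b])
        r <- .nn_batch_cpp(params, spec$layers, X, length(b), y_tr[b],
                           bn_state, TRUE, 0L, 0L)
        g <- r$grad + cfg$weight_decay * wd_mask * params
        if (cfg$optimizer == "adam") {
          tstep <- tstep + 1
          m1 <- 0.9 * m1 + 0.1 * g
          v2 <- 0.999 * v2 + 0.001 * g^2
          mh <- m1 / (1 - 0.9^tstep)
          vh <- v2 / (1 - 0.999^tstep)
          params <- params - lr * mh / (sqrt(vh) + 1e-8)
        } else {
          params <- params - lr * g
        }
        for (j in seq_along(bn_state)) {
          bn_state[[j]]$mean <- 0.9 * bn_state[[j]]$mean + 0.1 * as.numeric(r$bn_mean[[j]])
          bn_state[[j]]$var <- 0.9 * bn_state[[j]]$var + 0.1 * as.numeric(r$bn_var[[j]])
        }
      }
      etr <- eval_net(spec, params, bn_state, vols_tr, y_tr)
      eva <- if (use_val) eval_net(spec, params, bn_state, data[va], y[va]) else etr
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = etr$loss,
                                  train_acc = etr$acc, val_loss = eva$loss,
                                  val_acc = eva$acc)
      if (eva$loss < best$loss - 1e-8) {
        best <- list(loss = eva$loss, params = params, bn = bn_state,
                     epoch = epoch)
        patience_left <- cfg$early_stopping_patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    }
  })

  model$params <- best$params
  model$bn_state <- best$bn
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

#' @export
print.extractor_model <- function(x, ...) {
  cat(sprintf("<extractor_model %s: %s, %d epochs trained>\n", x$spec$kind,
              if (x$trained) "trained" else "initialized",
              nrow(x$history)))
  invisible(x)
}

#' Predict class probabilities for volumes
#' @param object an `extractor_model`; `newdata` list of `volume_sample`s.
#' @param newdata list of preprocessed `volume_sample`s.
#' @param ... unused.
#' @return matrix n x n_classes of softmax probabilities.
#' @export
predict.extractor_model <- function(object, newdata, ...) {
  check_volumes(newdata, object$spec)
  eval_net(object$spec, object$params, object$bn_state, newdata)$probs
}

#' Extract deep features at a named tap point
#'
#' Forward pass only (no weight update). `FC1`/`FC2` are the two 1000-unit
#' fully connected layers of the CNN, `FC4` the 1000-unit layer of the
#' residual network, and `FC3` is the virtual merge
#' `fc_concat_max(FC1, FC2)`.
#'
#' @param model an `extractor_model`.
#' @param data list of preprocessed `volume_sample`s (row order preserved).
#' @param tap tap name.
#' @return n x 1000 feature matrix with provenance attributes
#'   (`extractor`, `tap`).
#' @export
extract_features <- function(model, data, tap = "FC1") {
  stopifnot(inherits(model, "extractor_model"))
  check_volumes(data, model$spec)
  taps <- model$spec$tap_points
  if (identical(tap, "FC3")) {
    f1 <- extract_features(model, data, "FC1")
    f2 <- extract_features(model, data, "FC2")
    out <- fc_concat_max(f1, f2)
    attr(out, "extractor") <- model$spec$kind
    attr(out, "tap") <- "FC3"
    return(out)
  }
  if (!tap %in% names(taps))
    stop("unknown tap: ", tap, " (available: ",
         paste(c(names(taps), if (all(c("FC1", "FC2") %in% names(taps))) "FC3"),
               collapse = ", "), ")")
  X <- volumes_to_input(data)
  r <- .nn_batch_cpp(model$params, model$spec$layers, X, length(data),
                     integer(0), model$bn_state, FALSE, 2L, taps[[tap]])
  out <- r$act
  rownames(out) <- vapply(data, function(v) v$subject_id, "")
  colnames(out) <- sprintf("%s_%s_%04d", model$spec$kind, tolower(tap),
                           seq_len(ncol(out)))
  attr(out, "extractor") <- model$spec$kind
  attr(out, "tap") <- tap
  out
}

#' Merge two feature vectors by element-wise maximum
#'
#' Position-wise merge of two equal-length feature vectors (or row-aligned
#' matrices): each output element is the larger of the two inputs; when
#' they are equal the shared value is taken once, so no element is
#' duplicated.
#'
#' @param fv1,fv2 numeric vectors or matrices of identical dimension.
#' @return the element-wise maximum, same shape as the inputs.
#' @export
fc_concat_max <- function(fv1, fv2) {
  d1 <- dim(fv1) %||% length(fv1)
  d2 <- dim(fv2) %||% length(fv2)
  if (!identical(as.integer(d1), as.integer(d2)))
    stop("length mismatch: feature vectors must have identical dimensions")
  pmax(fv1, fv2)
}
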