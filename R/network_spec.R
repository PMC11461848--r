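# Layer manifests for the two volumetric extractors. Layers are enumerated
# explicitly and tap points are exposed by NAME (FC1/FC2/FC4; FC3 is the
# element-wise max merge of FC1 and FC2), so callers never depend on raw
# layer indices.

LAYER_CODES <- c(conv = 1L, relu = 2L, maxpool = 3L, batchnorm = 4L,
                 global_maxpool = 5L, dense = 6L, res_save = 7L, res_add = 8L,
                 softmax = 9L)

new_manifest <- function(input_shape) {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env$dims <- as.integer(input_shape)
  env$channels <- 1L
  env$poff <- 0
  env$save_stack <- integer(0)
  env
}

man_add <- function(env, kind, c_out = env$channels, pcnt = 0, aux = -1L,
                    dims_out = env$dims) {
  env$layers[[length(env$layers) + 1L]] <- list(
    kind = LAYER_CODES[[kind]], kind_name = kind,
    c_in = env$channels, c_out = as.integer(c_out),
    d_in = env$dims, d_out = as.integer(dims_out),
    poff = env$poff, pcnt = pcnt, aux = as.integer(aux))
  env$poff <- env$poff + pcnt
  env$channels <- as.integer(c_out)
  env$dims <- as.integer(dims_out)
  invisible(env)
}

man_conv <- function(env, c_out)
  man_add(env, "conv", c_out, pcnt = 27 * env$channels * c_out + c_out)
man_dense <- function(env, units)
  man_add(env, "dense", units, pcnt = env$channels * units + units,
          dims_out = c(1L, 1L, 1L))
man_bn <- function(env) man_add(env, "batchnorm", pcnt = 2 * env$channels)
man_pool <- function(env)
  man_add(env, "maxpool", dims_out = pmax(1L, env$dims %/% 2L))
man_res_save <- function(env) {
  man_add(env, "res_save")
  env$save_stack <- c(env$save_stack, length(env$layers))
  invisible(env)
}
man_res_add <- function(env) {
  j <- env$save_stack[length(env$save_stack)]
  env$save_stack <- env$save_stack[-length(env$save_stack)]
  c_save <- env$layers[[j]]$c_out
  pcnt <- if (c_save != env$channels) c_save * env$channels else 0
  man_add(env, "res_add", pcnt = pcnt, aux = j - 1L) # 0-based for C++
}

#' Build an extractor architecture manifest
#'
#' `cnn_variant3` is the ablation-selected CNN: three convolution blocks of
#' 2, 3 and 2 conv+ReLU layers (7 convolutions total), each block closed by
#' 2x2x2 max pooling and batch normalization, then global max pooling and
#' two 1000-unit fully connected layers (taps `FC1`, `FC2`) before the
#' softmax head. `resnet15` is the improved residual network: two initial
#' conv blocks, five residual stages (three residual units each; every unit
#' has two convolutions and a skip connection, with a 1x1x1 projection when
#' the channel count changes) each followed by max pooling, then a
#' 1000-unit fully connected tap (`FC4`) and the softmax head.
#' `cnn_base`, `cnn_variant1` and `cnn_variant2` are the smaller ablation
#' stages. Filter widths are `base_width`-scaled; tests shrink `base_width`
#' and the input shape together.
#'
#' @param kind one of `cnn_base`, `cnn_variant1`, `cnn_variant2`,
#'   `cnn_variant3`, `resnet15`.
#' @param input_shape voxel triple; minimum dim 8.
#' @param n_classes classifier width of the softmax head.
#' @param base_width filters in the first block (default 32; deeper blocks
#'   scale 2x and 4x).
#' @return object of class `network_spec` with the layer manifest, named tap
#'   points and total parameter count.
#' @export
build_extractor <- function(kind, input_shape = c(56L, 56L, 56L),
                            n_classes = 3L, base_width = 32L) {
  kinds <- c("cnn_base", "cnn_variant1", "cnn_variant2", "cnn_variant3",
             "resnet15")
  if (!kind %in% kinds)
    stop("unknown extractor kind: ", kind, " (expected one of ",
         paste(kinds, collapse = ", "), ")")
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 8L))
    stop("incompatible input shape: each dim must be >= 8")
  w <- as.integer(base_width)
  env <- new_manifest(input_shape)
  taps <- c()

  conv_block <- function(widths) {
    for (cw in widths) { man_conv(env, cw); man_add(env, "relu") }
    man_pool(env); man_bn(env)
  }
  fc_head <- function(with_1000 = TRUE) {
    man_add(env, "global_maxpool", dims_out = c(1L, 1L, 1L))
    if (with_1000) {
      man_dense(env, 1000L); man_add(env, "relu")
      taps["FC1"] <<- length(env$layers)
      man_dense(env, 1000L); man_add(env, "relu")
      taps["FC2"] <<- length(env$layers)
    }
    man_dense(env, n_classes)
    man_add(env, "softmax")
  }

  if (kind == "cnn_base") {
    conv_block(c(w, w)); fc_head(FALSE)
  } else if (kind == "cnn_variant1") {
    conv_block(c(w, w, w)); fc_head(FALSE)
  } else if (kind == "cnn_variant2") {
    conv_block(c(w, w)); conv_block(c(2L * w, 2L * w, 2L * w)); fc_head(TRUE)
  } else if (kind == "cnn_variant3") {
    conv_block(c(w, w))
    conv_block(c(2L * w, 2L * w, 2L * w))
    conv_block(c(4L * w, 4L * w))
    fc_head(TRUE)
  } else { # resnet15
    stage_w <- as.integer(w * c(1, 2, 2, 4, 4))
    # two initial conv blocks (conv + BN + ReLU)
    for (i in 1:2) { man_conv(env, w); man_bn(env); man_add(env, "relu") }
    for (sw in stage_w) {
      for (unit in 1:3) {
        man_res_save(env)
        man_conv(env, sw); man_bn(env); man_add(env, "relu")
        man_conv(env, sw); man_bn(env); man_add(env, "relu")
        man_res_add(env) # skip adds the unit input to the last ReLU output
      }
      man_pool(env)
    }
    man_add(env, "global_maxpool", dims_out = c(1L, 1L, 1L))
    man_dense(env, 1000L); man_add(env, "relu")
    taps["FC4"] <- length(env$layers)
    man_dense(env, n_classes)
    man_add(env, "softmax")
  }

  manifest <- do.call(rbind, lapply(seq_along(env$layers), function(i) {
    l <- env$layers[[i]]
    data.frame(index = i, layer_kind = l$kind_name, c_in = l$c_in,
               c_out = l$c_out,
               dims_out = paste(l$d_out, collapse = "x"),
               n_params = l$pcnt)
  }))
  structure(list(kind = kind, input_shape = input_shape,
                 n_classes = as.integer(n_classes), base_width = w,
                 layers = env$layers, layer_manifest = manifest,
                 tap_points = taps, n_params = env$poff),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec %s: %d layers, %s params, taps %s>\n", x$kind,
              length(x$layers), format(x$n_params, big.mark = ","),
              paste(names(x$tap_points), collapse = "/")))
  invisible(x)
}

#' Export an architecture manifest as JSON
#' @param spec a `network_spec`; `path` output file.
#' @param path output JSON path.
#' @export
write_manifest_json <- function(spec, path) {
  jsonlite::write_json(
    list(kind = spec$kind, input_shape = spec$input_shape,
         n_classes = spec$n_classes, base_width = spec$base_width,
         n_params = spec$n_params,
         tap_points = as.list(spec$tap_points),
         layers = spec$layer_manifest),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
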