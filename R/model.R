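# Backbone (50-layer bottleneck residual network) and full model assembly.

bottleneck_block <- function(cin, base, stride) {
  cout <- 4L * base
  list(
    kind = "bottleneck",
    conv1 = layer_conv(1, 1, cin, base),
    bn1 = layer_bn2d(base),
    conv2 = layer_conv(3, 3, base, base, stride = stride, pad = 1L),
    bn2 = layer_bn2d(base),
    conv3 = layer_conv(1, 1, base, cout),
    bn3 = layer_bn2d(cout),
    down = if (stride != 1L || cin != cout) {
      list(conv = layer_conv(1, 1, cin, cout, stride = stride),
           bn = layer_bn2d(cout))
    } else NULL
  )
}

fwd_bottleneck <- function(blk, x, training) {
  h <- op_relu(fwd_bn2d(blk$bn1, fwd_conv(blk$conv1, x), training))
  h <- op_relu(fwd_bn2d(blk$bn2, fwd_conv(blk$conv2, h), training))
  h <- fwd_bn2d(blk$bn3, fwd_conv(blk$conv3, h), training)
  skip <- if (is.null(blk$down)) x else {
    fwd_bn2d(blk$down$bn, fwd_conv(blk$down$conv, x), training)
  }
  op_relu(op_add(h, skip))
}

backbone_build <- function(cfg) {
  bases <- cfg$stage_channels %/% 4L
  stem_out <- bases[1]
  stages <- vector("list", 4)
  cin <- stem_out
  for (s in 1:4) {
    stride <- if (s == 1L) 1L else 2L
    blocks <- vector("list", cfg$block_counts[s])
    for (b in seq_len(cfg$block_counts[s])) {
      blocks[[b]] <- bottleneck_block(cin, bases[s], if (b == 1L) stride else 1L)
      cin <- 4L * bases[s]
    }
    stages[[s]] <- blocks
  }
  list(
    stem_conv = layer_conv(7, 7, cfg$in_channels, stem_out, stride = 2L, pad = 3L),
    stem_bn = layer_bn2d(stem_out),
    stages = stages
  )
}

backbone_forward <- function(bb, x, training) {
  h <- op_relu(fwd_bn2d(bb$stem_bn, fwd_conv(bb$stem_conv, x), training))
  h <- op_maxpool(h, 3L, 2L, 1L)
  out <- vector("list", 4)
  for (s in 1:4) {
    for (blk in bb$stages[[s]]) h <- fwd_bottleneck(blk, h, training)
    out[[s]] <- h
  }
  out
}

#' Architecture variants
#'
#' Valid variant selector strings, from the plain residual baseline to the
#' full model: `"resnet"` (backbone + classification head), `"resnet+ffb"`
#' (adds top-down guide-attention feature fusion), `"resnet+ffb+mcb"` (adds
#' the multi-scale context blocks), and `"ms-drcn"` (adds the soft-denoising
#' blocks; the complete model).
#'
#' @return Character vector of valid variant names.
#' @export
modelVariants <- function() {
  c("resnet", "resnet+ffb", "resnet+ffb+mcb", "ms-drcn")
}

#' Build the multi-scale denoising residual network
#'
#' Assembles the network: a 50-layer bottleneck residual backbone producing
#' four stage outputs at strides 4/8/16/32; per-stage paths that (in the full
#' model) apply a soft-denoising block at native channels, project to the
#' fusion width with a 1x1 convolution, and apply a multi-scale context
#' block; top-down guide-attention feature fusion; and a head that
#' concatenates the global average pool of the four fused maps into a single
#' fully connected layer. Ablation variants drop blocks per
#' [modelVariants()].
#'
#' @param config A [modelConfig()] object.
#' @param variant One of [modelVariants()].
#' @param classes Class vocabulary stored with the model (defaults to the
#'   standard four-way retinal vocabulary when `num_classes` is 4).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `msdrcn_model`.
#' @examples
#' \donttest{
#' m <- buildMSDRCN(deskConfig(), "ms-drcn", seed = 1)
#' x <- array(rnorm(64 * 64 * 2), dim = c(64, 64, 1, 2))
#' dim(modelForward(m, x))  # 2 x 4
#' }
#' @export
buildMSDRCN <- function(config = modelConfig(), variant = "ms-drcn",
                        classes = NULL, seed = NULL) {
  if (!variant %in% modelVariants()) {
    stop("unknown variant '", variant, "'; valid variants: ",
         paste(modelVariants(), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(classes)) {
    classes <- if (config$num_classes == 4L) {
      c("CNV", "DME", "Drusen", "Normal")
    } else {
      paste0("class", seq_len(config$num_classes))
    }
  }
  stopifnot(length(classes) == config$num_classes)
  has_ffb <- variant != "resnet"
  has_mcb <- variant %in% c("resnet+ffb+mcb", "ms-drcn")
  has_sdb <- variant == "ms-drcn"
  model <- list(
    config = config, variant = variant, classes = classes,
    backbone = backbone_build(config),
    sdb = if (has_sdb) {
      lapply(config$stage_channels, sdb_block, reduction = config$sdb_reduction)
    } else NULL,
    ffb = if (has_ffb) {
      ffb_block(config$stage_channels, config$fusion_channels,
                cascade = config$cascade_ffb)
    } else NULL,
    mcb = if (has_mcb) {
      lapply(1:4, function(i) {
        mcb_block(config$fusion_channels, config$mcb_reduction,
                  config$mcb_dilations)
      })
    } else NULL,
    head = layer_linear(
      if (has_ffb) 4L * config$fusion_channels else config$stage_channels[4],
      config$num_classes
    )
  )
  class(model) <- "msdrcn_model"
  model
}

# Forward pass returning tape nodes for the logits and named internals.
model_forward_nodes <- function(model, x, training) {
  xv <- ad_val(x)
  d <- dim(xv)
  if (length(d) != 4) stop("input must be a (H, W, C, N) array")
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("input spatial size must be divisible by 32; got ", d[1], "x", d[2])
  }
  if (d[3] != model$config$in_channels) {
    stop("input has ", d[3], " channels; model expects ",
         model$config$in_channels)
  }
  stages <- backbone_forward(model$backbone, x, training)
  if (is.null(model$ffb)) {
    feat <- op_gap_hw(stages[[4]])
    logits <- fwd_linear(model$head, feat)
    return(list(logits = logits, stages = stages, fused = NULL))
  }
  paths <- stages
  if (!is.null(model$sdb)) {
    paths <- lapply(1:4, function(i) {
      sdb_forward_node(model$sdb[[i]], paths[[i]], training)
    })
  }
  proj <- lapply(1:4, function(i) fwd_conv(model$ffb$proj[[i]], paths[[i]]))
  if (!is.null(model$mcb)) {
    proj <- lapply(1:4, function(i) {
      mcb_forward_node(model$mcb[[i]], proj[[i]], training)
    })
  }
  fused <- ffb_forward_node(model$ffb, proj, training, projected = TRUE)
  gaps <- lapply(fused, op_gap_hw)
  logits <- fwd_linear(model$head, op_concat_rows(gaps))
  list(logits = logits, stages = stages, fused = fused)
}

#' Run the network on a batch of images
#'
#' @param model A model from [buildMSDRCN()].
#' @param x Input array with dim `(H, W, C, N)` (a single `(H, W)` matrix or
#'   `(H, W, C)` array is promoted to a batch of one); spatial size must be
#'   divisible by 32.
#' @param training Use batch statistics in the batch-norm layers (training
#'   mode) instead of running statistics (evaluation mode).
#' @return Matrix of logits with dim `(N, num_classes)`.
#' @export
modelForward <- function(model, x, training = FALSE) {
  x <- as_feature_batch(x, model$config$in_channels)
  out <- model_forward_nodes(model, ad_input(x), training)
  lg <- t(ad_val(out$logits))
  colnames(lg) <- model$classes
  lg
}

as_feature_batch <- function(x, in_channels = 1L) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (length(d) == 2) d <- c(d, 1L, 1L)
  if (length(d) == 3) d <- c(d, 1L)
  dim(x) <- d
  x
}

#' Count trainable parameters
#'
#' @param model A model (or any nested block structure) containing trainable
#'   weights.
#' @return Total number of trainable scalar weights.
#' @export
countParameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$value), numeric(1)))
}

#' @export
print.msdrcn_model <- function(x, ...) {
  cat("Multi-scale denoising residual network\n")
  cat("  variant:    ", x$variant, "\n")
  cat("  classes:    ", paste(x$classes, collapse = ", "), "\n")
  cat("  parameters: ", format(countParameters(x), big.mark = ","), "\n")
  cat("  input:      ", x$config$in_channels, "x", x$config$input_size, "x",
      x$config$input_size, "\n")
  invisible(x)
}

#' Save a model checkpoint
#'
#' Writes the weight archive (RDS) plus a self-describing JSON sidecar with
#' the architecture configuration and class vocabulary.
#'
#' @param model A model from [buildMSDRCN()].
#' @param path Checkpoint file path (`.rds`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  payload <- list(
    state = collect_state(model),
    config = unclass(model$config),
    variant = model$variant,
    classes = model$classes
  )
  saveRDS(payload, path)
  jsonlite::write_json(
    list(package = "msdrcn", variant = model$variant, classes = model$classes,
         config = unclass(model$config)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [saveCheckpoint()].
#' @return The restored `msdrcn_model`.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  payload <- readRDS(path)
  cfg <- do.call(modelConfig, payload$config[setdiff(names(payload$config),
                                                     "pretrained_backbone")])
  model <- buildMSDRCN(cfg, payload$variant, payload$classes, seed = 0L)
  restore_state(model, payload$state)
  model
}
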