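#' Network architecture configuration
#'
#' Collects every architecture hyperparameter of the multi-scale denoising
#' residual convolutional network. Defaults reproduce the full-size model: a
#' 50-layer bottleneck residual backbone whose four stages emit 256/512/1024/
#' 2048 channels at strides 4/8/16/32, per-scale paths projected to a common
#' fusion width of 256 channels, a soft-denoising block whose hidden layer is
#' 1/16 of the stage channel count, and a multi-scale context block that
#' reduces to 1/8 of its input channels and splits into four dilated groups
#' (dilation rates 1-4).
#'
#' @param num_classes Number of output classes (default 4: CNV, DME, Drusen,
#'   Normal).
#' @param stage_channels Channel counts of the four backbone stage outputs;
#'   must be strictly increasing and divisible by 4 (bottleneck expansion).
#' @param fusion_channels Common channel width of the fused per-scale paths.
#'   Must be divisible by `mcb_reduction * mcb_group_count` so the context
#'   block's group split is exact.
#' @param sdb_reduction Channel reduction of the soft-denoising block's hidden
#'   fully connected layer.
#' @param mcb_reduction Channel reduction of the context block's 1x1 entry.
#' @param mcb_group_count Number of dilated groups in the context block.
#' @param mcb_dilations Dilation rate of each group's 3x3 convolution; length
#'   must equal `mcb_group_count`.
#' @param input_size Spatial side length the network expects (images are
#'   resized to `input_size` x `input_size`); must be divisible by 32.
#' @param in_channels Number of image channels (1 for grayscale B-scans).
#' @param block_counts Bottleneck blocks per backbone stage; the default
#'   `c(3, 4, 6, 3)` is the 50-layer arrangement.
#' @param cascade_ffb If `TRUE`, the feature fusion block reuses fused maps
#'   top-down (feature-pyramid style); the default `FALSE` fuses each scale
#'   with the projected next-coarser scale independently.
#' @param pretrained_backbone Reserved flag for initializing the backbone from
#'   pretrained weights; no weights ship with the package, so the default and
#'   only supported value is `FALSE`.
#'
#' @return An object of class `msdrcn_config`.
#' @export
modelConfig <- function(num_classes = 4L,
                        stage_channels = c(256L, 512L, 1024L, 2048L),
                        fusion_channels = 256L,
                        sdb_reduction = 16L,
                        mcb_reduction = 8L,
                        mcb_group_count = 4L,
                        mcb_dilations = c(1L, 2L, 3L, 4L),
                        input_size = 224L,
                        in_channels = 1L,
                        block_counts = c(3L, 4L, 6L, 3L),
                        cascade_ffb = FALSE,
                        pretrained_backbone = FALSE) {
  stopifnot(num_classes >= 2, length(stage_channels) == 4,
            length(block_counts) == 4, fusion_channels >= 1)
  if (any(diff(stage_channels) <= 0)) {
    stop("stage_channels must be strictly increasing")
  }
  if (length(mcb_dilations) != mcb_group_count) {
    stop("mcb_dilations must have one dilation rate per group (",
         mcb_group_count, ")")
  }
  if (fusion_channels %% (mcb_reduction * mcb_group_count) != 0) {
    stop("fusion_channels must be divisible by mcb_reduction * mcb_group_count = ",
         mcb_reduction * mcb_group_count,
         " so the context block's group split is exact")
  }
  if (input_size %% 32 != 0) {
    stop("input_size must be divisible by 32 (the backbone's total stride)")
  }
  if (isTRUE(pretrained_backbone)) {
    stop("no pretrained backbone weights are distributed with this package")
  }
  cfg <- list(
    num_classes = as.integer(num_classes),
    stage_channels = as.integer(stage_channels),
    fusion_channels = as.integer(fusion_channels),
    sdb_reduction = as.integer(sdb_reduction),
    mcb_reduction = as.integer(mcb_reduction),
    mcb_group_count = as.integer(mcb_group_count),
    mcb_dilations = as.integer(mcb_dilations),
    input_size = as.integer(input_size),
    in_channels = as.integer(in_channels),
    block_counts = as.integer(block_counts),
    cascade_ffb = isTRUE(cascade_ffb),
    pretrained_backbone = FALSE
  )
  class(cfg) <- "msdrcn_config"
  cfg
}

#' Compact configuration for desk-scale experiments
#'
#' A width-reduced instance of the same 50-layer topology (stage channels
#' 32/64/128/256, fusion width 32, 64x64 inputs) sized so that full training
#' runs on the synthetic phantom benchmark complete in minutes on one CPU
#' core. Every structural ratio of the full model (bottleneck expansion 4,
#' soft-denoising reduction 16, context-block reduction 8 with four dilated
#' groups) is preserved; the backbone depth is reduced to two bottleneck
#' blocks per stage.
#'
#' @param ... Overrides forwarded to [modelConfig()].
#' @return An object of class `msdrcn_config`.
#' @export
deskConfig <- function(...) {
  args <- list(
    stage_channels = c(32L, 64L, 128L, 256L),
    fusion_channels = 32L,
    mcb_reduction = 8L,
    mcb_group_count = 4L,
    input_size = 64L,
    block_counts = c(2L, 2L, 2L, 2L)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(modelConfig, args)
}

#' @export
print.msdrcn_config <- function(x, ...) {
  cat("Multi-scale denoising residual network configuration\n")
  cat("  classes:        ", x$num_classes, "\n")
  cat("  input:          ", x$in_channels, "x", x$input_size, "x", x$input_size, "\n")
  cat("  stage channels: ", paste(x$stage_channels, collapse = ", "), "\n")
  cat("  blocks/stage:   ", paste(x$block_counts, collapse = ", "), "\n")
  cat("  fusion width:   ", x$fusion_channels, "\n")
  cat("  SDB reduction:  ", x$sdb_reduction, "\n")
  cat("  MCB reduction:  ", x$mcb_reduction, ", dilations ",
      paste(x$mcb_dilations, collapse = ","), "\n", sep = "")
  invisible(x)
}
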