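# The three bespoke blocks: soft-denoising (SDB), multi-scale context (MCB),
# and guide-attention feature fusion (GA / FFB).

#' Soft thresholding
#'
#' The shrinkage operator at the heart of the soft-denoising block: values
#' within `[-tau, tau]` are set to zero and all others are shrunk toward zero
#' by `tau`, preserving sign. Odd, non-expansive and continuous in `x`.
#'
#' @param x Numeric scalar or array.
#' @param tau Non-negative threshold, broadcastable against `x`.
#' @return Array of the same shape as `x`.
#' @examples
#' softThreshold(c(-5, 1, 5), 2)  # -3 0 3
#' @export
softThreshold <- function(x, tau) {
  if (any(tau < 0)) stop("threshold tau must be non-negative")
  y <- sign(x) * pmax(abs(x) - tau, 0)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

# ---- soft-denoising block ---------------------------------------------------

# Squeeze-excite-style threshold estimator: GAP of |x| per channel, a
# bottleneck FC pair (C -> C/r -> C) with BN + ReLU between, sigmoid scaling,
# threshold = scaling * mean|x| per (channel, sample).
sdb_block <- function(channels, reduction = 16L) {
  hidden <- max(1L, channels %/% reduction)
  list(
    kind = "sdb", channels = channels,
    fc1 = layer_linear(channels, hidden, bias = TRUE),
    bn = layer_bn1d(hidden),
    fc2 = layer_linear(hidden, channels, bias = TRUE)
  )
}

sdb_threshold_node <- function(blk, x, training) {
  xv <- ad_val(x)
  if (dim(xv)[3] != blk$channels) {
    stop("soft-denoising block built for ", blk$channels,
         " channels but input has ", dim(xv)[3])
  }
  a <- op_absmean_hw(x)                                   # (C, N)
  z <- fwd_linear(blk$fc2, op_relu(fwd_bn1d(blk$bn, fwd_linear(blk$fc1, a), training)))
  scaling <- op_sigmoid(z)
  list(tau = op_mul(scaling, a), a = a)
}

sdb_forward_node <- function(blk, x, training) {
  th <- sdb_threshold_node(blk, x, training)
  op_add(op_soft_threshold(x, th$tau), x)
}

#' Soft-denoising block threshold
#'
#' Computes the learned per-(sample, channel) soft-thresholding level: the
#' spatial mean of `|x|` per channel is squeezed through a bottleneck
#' fully-connected pair and a sigmoid, and the resulting scaling in (0, 1)
#' multiplies the mean absolute activation. The threshold therefore always
#' lies strictly inside `[0, mean|x|)` whenever the channel is non-zero.
#'
#' @param block A soft-denoising block created by [sdbBlock()].
#' @param x Feature map array with dim `(H, W, C, N)`.
#' @param training Use batch statistics (`TRUE`) or running statistics in the
#'   internal batch normalization.
#' @return Matrix of thresholds with dim `(N, C)` (samples in rows).
#' @export
sdbThreshold <- function(block, x, training = FALSE) {
  th <- sdb_threshold_node(block, ad_input(x), training)
  t(ad_val(th$tau))
}

#' Soft-denoising block forward pass
#'
#' Applies learned soft thresholding to the feature map and adds the denoised
#' features back onto the input: `y = softThreshold(x, tau) + x`.
#'
#' @inheritParams sdbThreshold
#' @return Feature map of the same shape as `x`.
#' @export
sdbForward <- function(block, x, training = FALSE) {
  ad_val(sdb_forward_node(block, ad_input(x), training))
}

#' Construct a soft-denoising block
#'
#' @param channels Number of input channels.
#' @param reduction Hidden-layer reduction ratio (default 16).
#' @return A block object usable with [sdbThreshold()] and [sdbForward()].
#' @export
sdbBlock <- function(channels, reduction = 16L) {
  sdb_block(as.integer(channels), as.integer(reduction))
}

# ---- multi-scale context block ----------------------------------------------

# 1x1 Bconv reduces C -> C/reduction; the reduced map splits into equal
# channel groups, each passed through a 3x3 Bconv with its own dilation rate
# (padding = dilation keeps the spatial size); groups are concatenated, a 1x1
# Bconv expands back to C, and a skip connection adds the input.
mcb_block <- function(channels, reduction = 8L, dilations = c(1L, 2L, 3L, 4L)) {
  groups <- length(dilations)
  if (channels %% (reduction * groups) != 0) {
    stop("multi-scale context block needs channels divisible by ",
         reduction * groups, " (reduction ", reduction, " x ", groups,
         " groups); got ", channels)
  }
  red <- channels %/% reduction
  gch <- red %/% groups
  list(
    kind = "mcb", channels = channels, red = red, gch = gch,
    dilations = as.integer(dilations),
    reduce = layer_bconv(1, 1, channels, red),
    branches = lapply(dilations, function(d) {
      layer_bconv(3, 3, gch, gch, stride = 1L, pad = as.integer(d),
                  dil = as.integer(d))
    }),
    expand = layer_bconv(1, 1, red, channels)
  )
}

mcb_forward_node <- function(blk, x, training) {
  xv <- ad_val(x)
  if (dim(xv)[3] != blk$channels) {
    stop("multi-scale context block built for ", blk$channels,
         " channels but input has ", dim(xv)[3])
  }
  r <- fwd_bconv(blk$reduce, x, training)
  groups <- lapply(seq_along(blk$branches), function(i) {
    from <- (i - 1L) * blk$gch + 1L
    fwd_bconv(blk$branches[[i]], op_slice_c(r, from, from + blk$gch - 1L), training)
  })
  cc <- op_concat_c(groups)
  op_add(x, fwd_bconv(blk$expand, cc, training))
}

#' Construct a multi-scale context block
#'
#' @param channels Number of input (and output) channels; must be divisible by
#'   `reduction * length(dilations)`.
#' @param reduction Channel reduction of the 1x1 entry convolution (default 8).
#' @param dilations Dilation rates of the grouped 3x3 convolutions.
#' @return A block object usable with [mcbForward()].
#' @export
mcbBlock <- function(channels, reduction = 8L, dilations = c(1L, 2L, 3L, 4L)) {
  mcb_block(as.integer(channels), as.integer(reduction), as.integer(dilations))
}

#' Multi-scale context block forward pass
#'
#' @param block A block from [mcbBlock()].
#' @param x Feature map array with dim `(H, W, C, N)`.
#' @param training Batch-statistics switch for the internal batch norms.
#' @return Feature map of the same shape as `x`.
#' @export
mcbForward <- function(block, x, training = FALSE) {
  ad_val(mcb_forward_node(block, ad_input(x), training))
}

# ---- guide attention and feature fusion -------------------------------------

# GA fuses a fine-scale map with the next coarser map: the coarse map is
# bilinearly upsampled x2, both maps pass a BN, their element-wise product is
# sent through a 3x3 Bconv, and the result is added to the fine input.
ga_block <- function(channels) {
  list(
    kind = "ga", channels = channels,
    bn_fine = layer_bn2d(channels),
    bn_coarse = layer_bn2d(channels),
    conv = layer_bconv(3, 3, channels, channels, stride = 1L, pad = 1L)
  )
}

ga_forward_node <- function(blk, x_fine, x_coarse, training) {
  fv <- ad_val(x_fine); cv <- ad_val(x_coarse)
  if (dim(fv)[3] != dim(cv)[3]) {
    stop("guide attention requires equal channel counts; got ",
         dim(fv)[3], " and ", dim(cv)[3])
  }
  if (any(dim(fv)[1:2] != 2L * dim(cv)[1:2])) {
    stop("coarse map must be exactly half the fine map's spatial size")
  }
  u <- op_upsample2(x_coarse)
  f <- op_mul(fwd_bn2d(blk$bn_fine, x_fine, training),
              fwd_bn2d(blk$bn_coarse, u, training))
  op_add(fwd_bconv(blk$conv, f, training), x_fine)
}

#' Construct a guide attention block
#'
#' @param channels Common channel count of the two fused maps.
#' @return A block object usable with [gaForward()].
#' @export
gaBlock <- function(channels) ga_block(as.integer(channels))

#' Guide attention forward pass
#'
#' Fuses a spatially fine feature map with the next coarser one: the coarse
#' map is bilinearly upsampled by 2, both maps are batch-normalized, their
#' element-wise product passes a 3x3 Bconv, and the modulated feature is added
#' to the fine input.
#'
#' @param block A block from [gaBlock()].
#' @param x_fine Feature map with dim `(H, W, C, N)`.
#' @param x_coarse Feature map with dim `(H/2, W/2, C, N)`.
#' @param training Batch-statistics switch.
#' @return Feature map shaped like `x_fine`.
#' @export
gaForward <- function(block, x_fine, x_coarse, training = FALSE) {
  ad_val(ga_forward_node(block, ad_input(x_fine), ad_input(x_coarse), training))
}

# FFB: 1x1 projections bring the four stage outputs to the fusion width; the
# coarsest path passes through unchanged and each finer path is fused with
# the projected (default) or already-fused (cascade) next-coarser map via GA.
ffb_block <- function(stage_channels, fusion_channels, cascade = FALSE) {
  list(
    kind = "ffb", cascade = isTRUE(cascade),
    fusion_channels = as.integer(fusion_channels),
    proj = lapply(stage_channels, function(c) {
      layer_conv(1, 1, c, fusion_channels, bias = TRUE)
    }),
    ga = lapply(1:3, function(i) ga_block(fusion_channels))
  )
}

# `projected`: when TRUE the inputs are already at fusion width and the 1x1
# projections are skipped (the assembled model projects before its context
# blocks); standalone use projects raw stage outputs here.
ffb_forward_node <- function(blk, stages, training, projected = FALSE) {
  if (length(stages) != 4) stop("feature fusion expects 4 stage feature maps")
  dims <- lapply(stages, function(s) dim(ad_val(s)))
  for (i in 1:3) {
    if (any(dims[[i]][1:2] != 2L * dims[[i + 1]][1:2])) {
      stop("stage spatial sizes must halve along the list (stage ", i,
           " is not twice stage ", i + 1, ")")
    }
  }
  p <- if (projected) stages else {
    lapply(1:4, function(i) fwd_conv(blk$proj[[i]], stages[[i]]))
  }
  y <- vector("list", 4)
  y[[4]] <- p[[4]]
  for (i in 3:1) {
    coarse <- if (blk$cascade) y[[i + 1]] else p[[i + 1]]
    y[[i]] <- ga_forward_node(blk$ga[[i]], p[[i]], coarse, training)
  }
  y
}

#' Construct a feature fusion block
#'
#' @param stage_channels Channel counts of the four backbone stage outputs.
#' @param fusion_channels Common width after 1x1 projection (default 256).
#' @param cascade If `TRUE`, fuse each scale with the already-fused coarser
#'   output (feature-pyramid style) instead of the projected stage output.
#' @return A block object usable with [ffbForward()].
#' @export
ffbBlock <- function(stage_channels, fusion_channels = 256L, cascade = FALSE) {
  ffb_block(as.integer(stage_channels), as.integer(fusion_channels), cascade)
}

#' Feature fusion block forward pass
#'
#' Projects the four stage feature maps to the fusion width with 1x1
#' convolutions, passes the coarsest path through unchanged, and fuses each
#' finer path with the next-coarser one via guide attention.
#'
#' @param block A block from [ffbBlock()].
#' @param stages List of four feature maps at strides 4/8/16/32 (spatial sizes
#'   halving along the list).
#' @param training Batch-statistics switch.
#' @return List of four fused feature maps, each at the fusion width.
#' @export
ffbForward <- function(block, stages, training = FALSE) {
  nodes <- ffb_forward_node(block, lapply(stages, ad_input), training)
  lapply(nodes, ad_val)
}
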