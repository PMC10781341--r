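# Minimal reverse-mode autodifferentiation over dense arrays.
#
# Feature maps are 4-D arrays with dim (H, W, C, N); vector features (pooled
# descriptors, logits) are matrices with dim (F, N). A node is an environment
# holding a value and, while a tape is active, a backward closure plus parent
# references. backward() walks the tape in reverse creation order.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$recording <- FALSE

ad_tape_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  .ad$tape <- t
  .ad$recording <- TRUE
  invisible(t)
}

ad_tape_end <- function() {
  .ad$recording <- FALSE
  invisible(NULL)
}

ad_is_node <- function(x) inherits(x, "ad_node")

ad_val <- function(x) if (ad_is_node(x)) x$value else x

# A fresh tape node. `bwd` receives the output gradient and returns a list of
# gradients aligned with `parents` (NULL entries are skipped).
ad_node <- function(value, parents = list(), bwd = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "ad_node"
  if (.ad$recording && !is.null(bwd)) {
    e$parents <- parents
    e$bwd <- bwd
    t <- .ad$tape
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) {
      t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    }
    t$nodes[[t$n]] <- e
  }
  e
}

# A leaf input (no gradient tracking of its own producers).
ad_input <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

# A trainable parameter: persistent across forward passes, gradients
# accumulate until zeroed, carries an SGD momentum buffer.
ad_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- value * 0
  e$momentum <- value * 0
  class(e) <- c("ad_param", "ad_node")
  e
}

dim_or_len <- function(v) if (is.null(dim(v))) length(v) else dim(v)

ad_accum <- function(p, g) {
  if (is.null(g) || !ad_is_node(p)) return(invisible(NULL))
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(NULL)
}

# Reverse pass from `node`, seeding with `seed` (broadcast scalar allowed).
ad_backward <- function(node, seed = 1) {
  force(node)
  t <- .ad$tape
  if (is.null(t) || t$n == 0L) stop("no active tape to differentiate")
  sd <- if (length(seed) == 1L && length(node$value) > 1L) {
    array(seed, dim = dim_or_len(node$value))
  } else {
    seed
  }
  ad_accum(node, sd)
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$bwd(nd$grad)
    for (j in seq_along(nd$parents)) ad_accum(nd$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# ---- primitive operations ---------------------------------------------------

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- ad_val(x); wv <- ad_val(w)
  has_bias <- !is.null(b)
  bv <- if (has_bias) ad_val(b) else numeric(0)
  v <- cpp_conv2d_fwd(xv, wv, bv, has_bias, stride, pad, dil)
  ad_node(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(xv, wv, g, has_bias, stride, pad, dil, ad_is_node(x))
    list(r$gx, r$gw, if (has_bias) r$gb else NULL)
  })
}

# 2-D batch normalization. `running` is an environment with $mean and $var,
# updated in training mode with exponential momentum.
op_bn2d <- function(x, gamma, beta, running, training, momentum = 0.1, eps = 1e-5) {
  xv <- ad_val(x)
  if (training) {
    st <- cpp_bn2d_stats(xv)
    m <- st$mean; va <- st$var
    running$mean <- (1 - momentum) * running$mean + momentum * m
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    m <- running$mean; va <- running$var
  }
  invstd <- 1 / sqrt(va + eps)
  gv <- ad_val(gamma)
  v <- cpp_bn2d_fwd(xv, m, invstd, gv, ad_val(beta))
  ad_node(v, list(x, gamma, beta), function(g) {
    r <- cpp_bn2d_bwd(xv, m, invstd, gv, g, training)
    list(r$gx, r$dgamma, r$dbeta)
  })
}

# 1-D batch normalization over the sample dimension of an (F, N) matrix.
op_bn1d <- function(x, gamma, beta, running, training, momentum = 0.1, eps = 1e-5) {
  xv <- ad_val(x)
  n <- ncol(xv)
  if (training) {
    m <- rowMeans(xv)
    va <- rowMeans(xv^2) - m^2
    va[va < 0] <- 0
    running$mean <- (1 - momentum) * running$mean + momentum * m
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    m <- running$mean; va <- running$var
  }
  invstd <- 1 / sqrt(va + eps)
  gv <- ad_val(gamma)
  xhat <- (xv - m) * invstd
  v <- xhat * gv + ad_val(beta)
  ad_node(v, list(x, gamma, beta), function(g) {
    dgamma <- rowSums(g * xhat)
    dbeta <- rowSums(g)
    gx <- if (training) {
      (gv * invstd) * (g - rowMeans(g) - xhat * rowMeans(g * xhat))
    } else {
      g * gv * invstd
    }
    list(gx, dgamma, dbeta)
  })
}

op_relu <- function(x) {
  xv <- ad_val(x)
  v <- pmax(xv, 0)
  dim(v) <- dim_or_len(xv)
  ad_node(v, list(x), function(g) list(g * (xv > 0)))
}

op_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-ad_val(x)))
  ad_node(v, list(x), function(g) list(g * v * (1 - v)))
}

op_add <- function(a, b) {
  ad_node(ad_val(a) + ad_val(b), list(a, b), function(g) list(g, g))
}

op_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# Soft thresholding of a feature map by a per-(channel, sample) threshold
# matrix tau with dim (C, N), broadcast over the spatial grid.
op_soft_threshold <- function(x, tau) {
  xv <- ad_val(x); tv <- ad_val(tau)
  d <- dim(xv)
  hw <- d[1] * d[2]
  tfull <- array(rep(as.vector(tv), each = hw), dim = d)
  mag <- pmax(abs(xv) - tfull, 0)
  v <- sign(xv) * mag
  dim(v) <- d
  mask <- abs(xv) > tfull
  ad_node(v, list(x, tau), function(g) {
    gx <- g * mask
    gt <- -sign(xv) * g * mask
    gtau <- colSums(matrix(gt, nrow = hw))
    dim(gtau) <- dim(tv)
    list(gx, gtau)
  })
}

# Spatial mean of |x| per (channel, sample): the GAP-of-absolute-values
# descriptor feeding the soft-denoising block, dim (C, N).
op_absmean_hw <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  hw <- d[1] * d[2]
  v <- colMeans(matrix(abs(xv), nrow = hw))
  dim(v) <- c(d[3], d[4])
  ad_node(v, list(x), function(g) {
    gb <- array(rep(as.vector(g), each = hw), dim = d)
    list(sign(xv) * gb / hw)
  })
}

# Global average pooling over the spatial grid, dim (C, N).
op_gap_hw <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  hw <- d[1] * d[2]
  v <- colMeans(matrix(xv, nrow = hw))
  dim(v) <- c(d[3], d[4])
  ad_node(v, list(x), function(g) {
    list(array(rep(as.vector(g), each = hw), dim = d) / hw)
  })
}

op_linear <- function(x, w, b = NULL) {
  xv <- ad_val(x); wv <- ad_val(w)
  v <- wv %*% xv
  if (!is.null(b)) v <- v + ad_val(b)
  ad_node(v, list(x, w, b), function(g) {
    list(crossprod(wv, g), g %*% t(xv), if (!is.null(b)) rowSums(g) else NULL)
  })
}

op_concat_c <- function(xs) {
  vs <- lapply(xs, ad_val)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (v in vs) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  ends <- cumsum(cs)
  starts <- ends - cs + 1
  ad_node(out, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, , starts[i]:ends[i], , drop = FALSE])
  })
}

op_slice_c <- function(x, from, to) {
  xv <- ad_val(x)
  v <- xv[, , from:to, , drop = FALSE]
  ad_node(v, list(x), function(g) {
    gx <- array(0, dim = dim(xv))
    gx[, , from:to, ] <- g
    list(gx)
  })
}

op_concat_rows <- function(xs) {
  vs <- lapply(xs, ad_val)
  rows <- vapply(vs, nrow, numeric(1))
  v <- do.call(rbind, vs)
  ends <- cumsum(rows)
  starts <- ends - rows + 1
  ad_node(v, xs, function(g) {
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

op_upsample2 <- function(x) {
  xv <- ad_val(x)
  v <- cpp_upsample2_fwd(xv)
  ad_node(v, list(x), function(g) list(cpp_upsample2_bwd(g, dim(xv))))
}

op_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  xv <- ad_val(x)
  r <- cpp_maxpool_fwd(xv, k, stride, pad)
  ad_node(r$out, list(x), function(g) list(cpp_maxpool_bwd(g, r$argmax, dim(xv))))
}

# Weighted cross-entropy over logits (K, N). Normalized by the summed weights
# of the realized labels, so a balanced set reproduces the unweighted mean.
op_wce <- function(logits, labels, weights) {
  lv <- ad_val(logits)
  n <- ncol(lv)
  mx <- apply(lv, 2, max)
  sh <- sweep(lv, 2, mx)
  lse <- log(colSums(exp(sh))) + mx
  idx <- cbind(labels, seq_len(n))
  logp_y <- lv[idx] - lse
  wy <- weights[labels]
  wsum <- sum(wy)
  v <- sum(-logp_y * wy) / wsum
  ad_node(v, list(logits), function(g) {
    p <- exp(sweep(lv, 2, lse))
    p[idx] <- p[idx] - 1
    list(g * sweep(p, 2, wy, "*") / wsum)
  })
}
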