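# Straight-line reference implementations used as independent oracles for
# the network blocks, written with plain loops and base matrix ops only.

naive_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(w); kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (wo in 1:Wo) for (ho in 1:Ho) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ci in 1:C) for (kj in 1:kw) for (ki in 1:kh) {
      hi <- (ho - 1) * stride - pad + (ki - 1) * dil + 1
      wi <- (wo - 1) * stride - pad + (kj - 1) * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[hi, wi, ci, n] * w[ki, kj, ci, co]
      }
    }
    out[ho, wo, co, n] <- acc
  }
  out
}

# Evaluation-mode batch norm from running statistics.
naive_bn_eval <- function(x, ly, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (c in seq_len(d[3])) {
    out[, , c, ] <- (x[, , c, ] - ly$running$mean[c]) /
      sqrt(ly$running$var[c] + eps) * ly$gamma$value[c] + ly$beta$value[c]
  }
  out
}

naive_bconv_eval <- function(x, ly) {
  pmax(naive_bn_eval(naive_conv2d(x, ly$conv$w$value, NULL, ly$conv$stride,
                                  ly$conv$pad, ly$conv$dil), ly$bn), 0)
}

# Bilinear x2 upsampling with the half-pixel mapping.
naive_upsample2 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  out <- array(0, c(2 * H, 2 * W, d[3], d[4]))
  coord <- function(o, n) min(max((o + 0.5) / 2 - 0.5, 0), n - 1)
  for (n in 1:d[4]) for (c in 1:d[3]) for (wo in 1:(2 * W)) for (ho in 1:(2 * H)) {
    sy <- coord(ho - 1, H); sx <- coord(wo - 1, W)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
    fy <- sy - y0; fx <- sx - x0
    out[ho, wo, c, n] <-
      (1 - fx) * ((1 - fy) * x[y0 + 1, x0 + 1, c, n] + fy * x[y1 + 1, x0 + 1, c, n]) +
      fx * ((1 - fy) * x[y0 + 1, x1 + 1, c, n] + fy * x[y1 + 1, x1 + 1, c, n])
  }
  out
}

soft_thr_ref <- function(x, tau) {
  y <- x
  y[x > tau] <- (x - tau)[x > tau]
  y[x < -tau] <- (x + tau)[x < -tau]
  y[x >= -tau & x <= tau] <- 0
  y
}

# Straight-line soft-denoising block, evaluation mode.
naive_sdb <- function(blk, x, eps = 1e-5) {
  d <- dim(x)
  a <- apply(abs(x), c(3, 4), mean)            # (C, N)
  h <- blk$fc1$w$value %*% a + blk$fc1$b$value
  h <- (h - blk$bn$running$mean) / sqrt(blk$bn$running$var + eps) *
    blk$bn$gamma$value + blk$bn$beta$value
  h <- pmax(h, 0)
  z <- blk$fc2$w$value %*% h + blk$fc2$b$value
  tau <- (1 / (1 + exp(-z))) * a
  y <- x
  for (n in 1:d[4]) for (c in 1:d[3]) {
    y[, , c, n] <- soft_thr_ref(x[, , c, n], tau[c, n]) + x[, , c, n]
  }
  list(y = y, tau = tau)
}

# Straight-line multi-scale context block, evaluation mode.
naive_mcb <- function(blk, x) {
  r <- naive_bconv_eval(x, blk$reduce)
  gs <- lapply(seq_along(blk$branches), function(i) {
    from <- (i - 1) * blk$gch + 1
    naive_bconv_eval(r[, , from:(from + blk$gch - 1), , drop = FALSE],
                     blk$branches[[i]])
  })
  cc <- array(0, dim = dim(r))
  at <- 0
  for (g in gs) {
    cc[, , at + seq_len(dim(g)[3]), ] <- g
    at <- at + dim(g)[3]
  }
  x + naive_bconv_eval(cc, blk$expand)
}

# Straight-line guide attention, evaluation mode.
naive_ga <- function(blk, xf, xc) {
  u <- naive_upsample2(xc)
  f <- naive_bn_eval(xf, blk$bn_fine) * naive_bn_eval(u, blk$bn_coarse)
  naive_bconv_eval(f, blk$conv) + xf
}

rand_fmap <- function(H, W, C, N) {
  array(rnorm(H * W * C * N), dim = c(H, W, C, N))
}

# Randomize a block's batch-norm running statistics and FC/conv weights so
# oracle comparisons exercise non-trivial affine parameters.
randomize_bn <- function(ly) {
  ly$running$mean <- rnorm(length(ly$running$mean), sd = 0.3)
  ly$running$var <- runif(length(ly$running$var), 0.5, 1.5)
  ly$gamma$value <- runif(length(ly$gamma$value), 0.5, 1.5)
  ly$beta$value <- rnorm(length(ly$beta$value), sd = 0.2)
  invisible(NULL)
}
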