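# Finite-difference gradient verification of every differentiable primitive.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] - eps
    x2[i] <- x2[i] + eps
    g[i] <- (f(x2) - f(x1)) / (2 * eps)
  }
  g
}

# Quadratic readout so the seed gradient is just the output value.
sq_loss_backward <- function(out) {
  loss <- msdrcn:::ad_node(sum(msdrcn:::ad_val(out)^2) / 2, list(out),
                           function(g) list(g * msdrcn:::ad_val(out)))
  msdrcn:::ad_backward(loss)
}

test_that("convolution gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(5 * 6 * 3 * 2), dim = c(5, 6, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4) * 0.4, dim = c(3, 3, 3, 4))
  b <- rnorm(4)
  for (cfg in list(c(1, 1, 1), c(2, 1, 1), c(1, 3, 3))) {
    st <- cfg[1]; pd <- cfg[2]; dl <- cfg[3]
    f <- function(xx) sum(msdrcn:::cpp_conv2d_fwd(xx, w, b, TRUE, st, pd, dl)^2) / 2
    fw <- function(ww) sum(msdrcn:::cpp_conv2d_fwd(x, ww, b, TRUE, st, pd, dl)^2) / 2
    msdrcn:::ad_tape_begin()
    xn <- msdrcn:::ad_input(x); wn <- msdrcn:::ad_input(w)
    out <- msdrcn:::op_conv2d(xn, wn, msdrcn:::ad_input(b), st, pd, dl)
    sq_loss_backward(out)
    msdrcn:::ad_tape_end()
    expect_lt(max(abs(xn$grad - num_grad(f, x))), 1e-6)
    expect_lt(max(abs(wn$grad - num_grad(fw, w))), 1e-6)
  }
})

test_that("batch norm gradients match finite differences in both modes", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 3 * 3), dim = c(4, 4, 3, 3))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
  rm0 <- rnorm(3) * 0.2; rv0 <- runif(3, 0.5, 2)
  mk <- function() {
    e <- new.env(); e$mean <- rm0; e$var <- rv0; e
  }
  for (train in c(TRUE, FALSE)) {
    f <- function(xx) {
      sum(msdrcn:::ad_val(msdrcn:::op_bn2d(msdrcn:::ad_input(xx),
        msdrcn:::ad_input(gamma), msdrcn:::ad_input(beta), mk(), train))^2) / 2
    }
    msdrcn:::ad_tape_begin()
    xn <- msdrcn:::ad_input(x)
    gn <- msdrcn:::ad_input(gamma)
    out <- msdrcn:::op_bn2d(xn, gn, msdrcn:::ad_input(beta), mk(), train)
    sq_loss_backward(out)
    msdrcn:::ad_tape_end()
    expect_lt(max(abs(xn$grad - num_grad(f, x))), 1e-6)
    fg <- function(gg) {
      sum(msdrcn:::ad_val(msdrcn:::op_bn2d(msdrcn:::ad_input(x),
        msdrcn:::ad_input(gg), msdrcn:::ad_input(beta), mk(), train))^2) / 2
    }
    expect_lt(max(abs(gn$grad - num_grad(fg, gamma))), 1e-6)
  }
})

test_that("pooling, upsampling, soft-threshold and loss gradients are exact", {
  set.seed(13)
  x <- array(rnorm(4 * 5 * 3 * 2), dim = c(4, 5, 3, 2))
  # max pooling (weighted readout to break symmetry)
  f <- function(xx) {
    o <- msdrcn:::cpp_maxpool_fwd(xx, 3L, 2L, 1L)$out
    sum(o * seq_along(o))
  }
  msdrcn:::ad_tape_begin()
  xn <- msdrcn:::ad_input(x)
  out <- msdrcn:::op_maxpool(xn)
  sv <- array(seq_along(out$value), dim = dim(out$value))
  loss <- msdrcn:::ad_node(sum(out$value * sv), list(out), function(g) list(g * sv))
  msdrcn:::ad_backward(loss)
  msdrcn:::ad_tape_end()
  expect_lt(max(abs(xn$grad - num_grad(f, x, 1e-6))), 1e-5)
  # bilinear upsampling
  f <- function(xx) sum(msdrcn:::cpp_upsample2_fwd(xx)^2) / 2
  msdrcn:::ad_tape_begin()
  xn <- msdrcn:::ad_input(x)
  sq_loss_backward(msdrcn:::op_upsample2(xn))
  msdrcn:::ad_tape_end()
  expect_lt(max(abs(xn$grad - num_grad(f, x))), 1e-6)
  # soft threshold in both arguments
  tau <- matrix(runif(3 * 2, 0.2, 0.8), 3, 2)
  f <- function(xx) {
    sum(msdrcn:::ad_val(msdrcn:::op_soft_threshold(msdrcn:::ad_input(xx),
                                                   msdrcn:::ad_input(tau)))^2) / 2
  }
  ft <- function(tt) {
    sum(msdrcn:::ad_val(msdrcn:::op_soft_threshold(msdrcn:::ad_input(x),
                                                   msdrcn:::ad_input(tt)))^2) / 2
  }
  msdrcn:::ad_tape_begin()
  xn <- msdrcn:::ad_input(x); tn <- msdrcn:::ad_input(tau)
  sq_loss_backward(msdrcn:::op_soft_threshold(xn, tn))
  msdrcn:::ad_tape_end()
  expect_lt(max(abs(xn$grad - num_grad(f, x))), 1e-6)
  expect_lt(max(abs(tn$grad - num_grad(ft, tau))), 1e-6)
  # weighted cross-entropy
  lg <- matrix(rnorm(4 * 6), 4, 6)
  lab <- sample(1:4, 6, TRUE)
  wt <- runif(4, 0.5, 2)
  f <- function(ll) msdrcn:::ad_val(msdrcn:::op_wce(msdrcn:::ad_input(ll), lab, wt))
  msdrcn:::ad_tape_begin()
  ln <- msdrcn:::ad_input(lg)
  msdrcn:::ad_backward(msdrcn:::op_wce(ln, lab, wt))
  msdrcn:::ad_tape_end()
  expect_lt(max(abs(ln$grad - num_grad(f, lg))), 1e-8)
})

test_that("weighted cross-entropy with unit weights equals the unweighted mean", {
  set.seed(14)
  lg <- matrix(rnorm(4 * 12), 4, 12)
  lab <- rep(1:4, 3)
  balanced <- msdrcn:::ad_val(msdrcn:::op_wce(msdrcn:::ad_input(lg), lab,
                                              classWeights(c(3, 3, 3, 3))))
  p <- apply(lg, 2, function(v) exp(v - max(v)) / sum(exp(v - max(v))))
  manual <- mean(-log(p[cbind(lab, seq_along(lab))]))
  expect_equal(balanced, manual, tolerance = 1e-12)
})
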