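# Block-level behavior: closed forms, bounds, residual identities, and
# agreement with straight-line reference implementations.

test_that("softThreshold implements the piecewise shrinkage formula", {
  expect_equal(softThreshold(5, 2), 3)
  expect_equal(softThreshold(-5, 2), -3)
  expect_equal(softThreshold(1, 2), 0)
  expect_equal(softThreshold(c(-2, 2), 2), c(0, 0))
  set.seed(21)
  x <- array(rnorm(200), dim = c(10, 20))
  expect_identical(softThreshold(x, 0), x)
  expect_error(softThreshold(x, -0.1), "non-negative")
  tau <- 0.7
  y <- softThreshold(x, tau)
  # odd, non-expansive, magnitude shrinkage
  expect_equal(softThreshold(-x, tau), -y)
  expect_true(all(abs(y) <= abs(x)))
  expect_equal(abs(y), pmax(abs(x) - tau, 0))
  expect_true(all(sign(y) == sign(x) | y == 0))
})

test_that("soft-denoising threshold lies in [0, mean|x|) and matches its closed forms", {
  set.seed(22)
  blk <- sdbBlock(16, reduction = 16)
  # all-zero input forces tau = 0
  x0 <- array(0, dim = c(6, 6, 16, 2))
  expect_true(all(sdbThreshold(blk, x0) == 0))
  expect_true(all(sdbForward(blk, x0) == 0))
  # zeroed FC stack gives sigmoid(0) = 1/2, tau = mean|x| / 2
  blk0 <- sdbBlock(16)
  for (p in msdrcn:::collect_params(blk0)) p$value[] <- 0
  x <- rand_fmap(6, 6, 16, 3)
  tau <- sdbThreshold(blk0, x)
  expect_equal(tau, t(apply(abs(x), c(3, 4), mean)) / 2, tolerance = 1e-12)
  # strict bound across random blocks (moderate weights keep the sigmoid
  # away from 1.0 at double precision, where the bound is only non-strict)
  for (i in 1:30) {
    b <- sdbBlock(8, reduction = 4)
    for (p in msdrcn:::collect_params(b)) p$value[] <- rnorm(length(p$value), sd = 0.5)
    xx <- rand_fmap(4, 5, 8, 2)
    tt <- sdbThreshold(b, xx)
    m <- t(apply(abs(xx), c(3, 4), mean))
    expect_true(all(tt >= 0))
    expect_true(all(tt < m))
  }
  # extreme weights can saturate the sigmoid; tau still never exceeds mean|x|
  bex <- sdbBlock(8, reduction = 4)
  for (p in msdrcn:::collect_params(bex)) p$value[] <- rnorm(length(p$value), sd = 50)
  xx <- rand_fmap(4, 5, 8, 2)
  expect_true(all(sdbThreshold(bex, xx) <= t(apply(abs(xx), c(3, 4), mean))))
  # channel mismatch errors
  expect_error(sdbThreshold(blk, rand_fmap(4, 4, 8, 1)), "channels")
})

test_that("soft-denoising forward matches the straight-line reference", {
  set.seed(23)
  for (i in 1:5) {
    blk <- sdbBlock(16)
    for (p in msdrcn:::collect_params(blk)) p$value[] <- rnorm(length(p$value))
    randomize_bn(blk$bn)
    x <- rand_fmap(5, 7, 16, 2)
    ref <- naive_sdb(blk, x)
    expect_equal(sdbForward(blk, x), ref$y, tolerance = 1e-10)
    expect_equal(sdbThreshold(blk, x), t(ref$tau), tolerance = 1e-10)
  }
  # piecewise consequence: y = x inside the dead zone, 2x -/+ tau outside
  blk <- sdbBlock(8, reduction = 4)
  x <- rand_fmap(6, 6, 8, 2)
  tau <- t(sdbThreshold(blk, x))  # (C, N)
  y <- sdbForward(blk, x)
  tf <- array(rep(as.vector(tau), each = 36), dim = dim(x))
  inside <- abs(x) <= tf
  expect_equal(y[inside], x[inside])
  hi <- x > tf
  expect_equal(y[hi], (2 * x - tf)[hi], tolerance = 1e-12)
  lo <- x < -tf
  expect_equal(y[lo], (2 * x + tf)[lo], tolerance = 1e-12)
})

test_that("multi-scale context block preserves shape and matches the reference", {
  set.seed(24)
  blk <- mcbBlock(32)
  for (ly in c(list(blk$reduce$bn, blk$expand$bn),
               lapply(blk$branches, function(b) b$bn))) {
    randomize_bn(ly)
  }
  x <- rand_fmap(10, 10, 32, 2)
  y <- mcbForward(blk, x)
  expect_identical(dim(y), dim(x))
  expect_equal(y, naive_mcb(blk, x), tolerance = 1e-10)
  # indivisible channel count names the requirement
  expect_error(mcbBlock(33), "divisible by 32")
  expect_error(mcbForward(blk, rand_fmap(4, 4, 64, 1)), "channels")
})

test_that("zeroed convolutions reduce MCB to the identity", {
  set.seed(25)
  blk <- mcbBlock(32)
  for (nm in c("reduce", "expand")) blk[[nm]]$conv$w$value[] <- 0
  for (br in blk$branches) br$conv$w$value[] <- 0
  x <- rand_fmap(8, 8, 32, 2)
  expect_equal(mcbForward(blk, x), x, tolerance = 1e-12)
})

test_that("a dilation-4 3x3 kernel has a 9x9 receptive footprint", {
  x <- array(0, dim = c(21, 21, 1, 1))
  x[11, 11, 1, 1] <- 1
  w <- array(1, dim = c(3, 3, 1, 1))
  y <- msdrcn:::cpp_conv2d_fwd(x, w, numeric(0), FALSE, 1L, 4L, 4L)
  nz <- which(y != 0, arr.ind = TRUE)
  expect_equal(range(nz[, 1]), c(11 - 4, 11 + 4))
  expect_equal(range(nz[, 2]), c(11 - 4, 11 + 4))
})

test_that("guide attention obeys its shape contract, identity, and reference", {
  set.seed(26)
  blk <- gaBlock(8)
  xf <- rand_fmap(12, 12, 8, 2)
  xc <- rand_fmap(6, 6, 8, 2)
  y <- gaForward(blk, xf, xc)
  expect_identical(dim(y), dim(xf))
  # zero conv weights: residual identity
  blk0 <- gaBlock(8)
  blk0$conv$conv$w$value[] <- 0
  expect_equal(gaForward(blk0, xf, xc), xf, tolerance = 1e-12)
  # reference agreement with randomized BN statistics
  for (ly in list(blk$bn_fine, blk$bn_coarse, blk$conv$bn)) randomize_bn(ly)
  expect_equal(gaForward(blk, xf, xc), naive_ga(blk, xf, xc), tolerance = 1e-10)
  # errors
  expect_error(gaForward(blk, xf, rand_fmap(6, 6, 4, 2)), "channel")
  expect_error(gaForward(blk, xf, rand_fmap(5, 5, 8, 2)), "half")
})

test_that("feature fusion projects all scales to the fusion width top-down", {
  set.seed(27)
  sc <- c(8L, 16L, 32L, 64L)
  blk <- ffbBlock(sc, fusion_channels = 8L)
  stages <- lapply(1:4, function(i) {
    rand_fmap(32 / 2^(i - 1), 32 / 2^(i - 1), sc[i], 2)
  })
  ys <- ffbForward(blk, stages)
  for (i in 1:4) {
    expect_identical(dim(ys[[i]]), c(dim(stages[[i]])[1:2], 8L, 2L))
  }
  # the coarsest output is exactly the 1x1-projected input
  p4 <- naive_conv2d(stages[[4]], blk$proj[[4]]$w$value,
                              blk$proj[[4]]$b$value)
  expect_equal(ys[[4]], p4, tolerance = 1e-10)
  # zero GA convolutions: every output is its projected input
  blk0 <- ffbBlock(sc, fusion_channels = 8L)
  for (g in blk0$ga) g$conv$conv$w$value[] <- 0
  ys0 <- ffbForward(blk0, stages)
  for (i in 1:4) {
    pi <- naive_conv2d(stages[[i]], blk0$proj[[i]]$w$value,
                                blk0$proj[[i]]$b$value)
    expect_equal(ys0[[i]], pi, tolerance = 1e-10)
  }
  expect_error(ffbForward(blk, stages[1:3]), "4 stage")
  bad <- stages; bad[[2]] <- rand_fmap(20, 20, 16, 2)
  expect_error(ffbForward(blk, bad), "halve")
})
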