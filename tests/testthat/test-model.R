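# Assembled-network contracts: shapes, determinism, parameter accounting,
# gradient flow through every component, checkpoint round-trips.

small_cfg <- function(...) deskConfig(input_size = 32L, ...)

test_that("forward pass yields one finite logit row per sample and class", {
  m <- buildMSDRCN(small_cfg(), "ms-drcn", seed = 31)
  x <- array(rnorm(32 * 32 * 2), dim = c(32, 32, 1, 2))
  lg <- modelForward(m, x)
  expect_identical(dim(lg), c(2L, 4L))
  expect_true(all(is.finite(lg)))
  m3 <- buildMSDRCN(small_cfg(num_classes = 3L), "ms-drcn", seed = 31)
  expect_identical(dim(modelForward(m3, x)), c(2L, 3L))
  # evaluation mode is deterministic
  expect_identical(lg, modelForward(m, x))
  # bad inputs
  expect_error(modelForward(m, array(0, dim = c(33, 33, 1, 1))), "divisible by 32")
  expect_error(modelForward(m, array(0, dim = c(32, 32, 3, 1))), "channels")
  expect_error(buildMSDRCN(small_cfg(), "vgg"), "resnet")
})

test_that("parameter counting sums trainable weight arrays", {
  conv <- msdrcn:::layer_conv(3, 3, 1, 8, bias = TRUE)
  expect_equal(countParameters(conv), 3 * 3 * 1 * 8 + 8)
  fc <- msdrcn:::layer_linear(10, 4)
  expect_equal(countParameters(fc), 44)
  expect_equal(countParameters(list()), 0)
})

test_that("ablation variants nest by parameter count", {
  cfg <- small_cfg()
  counts <- vapply(modelVariants(), function(v) {
    countParameters(buildMSDRCN(cfg, v, seed = 1))
  }, numeric(1))
  expect_true(all(diff(counts[c("resnet", "resnet+ffb", "resnet+ffb+mcb",
                                "ms-drcn")]) > 0))
  # the SDB increment equals the closed-form FC parameter count
  hidden <- pmax(1, cfg$stage_channels %/% cfg$sdb_reduction)
  sdb_params <- sum(2 * cfg$stage_channels * hidden + hidden + cfg$stage_channels +
                      2 * hidden)  # FC1 + FC2 weights+biases + BN affine
  expect_equal(counts[["ms-drcn"]] - counts[["resnet+ffb+mcb"]], sdb_params)
})

test_that("one optimization step reaches every component with gradient", {
  set.seed(32)
  for (variant in modelVariants()) {
    m <- buildMSDRCN(small_cfg(), variant, seed = 33)
    x <- array(rnorm(32 * 32 * 4), dim = c(32, 32, 1, 4))
    y <- c(1L, 2L, 3L, 4L)
    msdrcn:::ad_tape_begin()
    out <- msdrcn:::model_forward_nodes(m, msdrcn:::ad_input(x), TRUE)
    loss <- msdrcn:::op_wce(out$logits, y, rep(1, 4))
    msdrcn:::ad_backward(loss)
    msdrcn:::ad_tape_end()
    expect_true(is.finite(msdrcn:::ad_val(loss)))
    components <- Filter(Negate(is.null),
                         list(backbone = m$backbone, sdb = m$sdb,
                              ffb = m$ffb, mcb = m$mcb, head = m$head))
    for (nm in names(components)) {
      gnorm <- sum(vapply(msdrcn:::collect_params(components[[nm]]),
                          function(p) sum(abs(p$grad)), numeric(1)))
      expect_gt(gnorm, 0)
    }
  }
})

test_that("repeated SGD steps on one batch reduce the training loss", {
  set.seed(34)
  m <- buildMSDRCN(small_cfg(), "ms-drcn", seed = 35)
  params <- msdrcn:::collect_params(m)
  x <- array(rnorm(32 * 32 * 8), dim = c(32, 32, 1, 8))
  y <- rep(1:4, 2)
  losses <- numeric(6)
  for (i in seq_along(losses)) {
    msdrcn:::ad_tape_begin()
    out <- msdrcn:::model_forward_nodes(m, msdrcn:::ad_input(x), TRUE)
    loss <- msdrcn:::op_wce(out$logits, y, rep(1, 4))
    msdrcn:::ad_backward(loss)
    msdrcn:::ad_tape_end()
    losses[i] <- msdrcn:::ad_val(loss)
    msdrcn:::sgd_step(params, 0.01, 0.9, 0)
  }
  expect_lt(losses[length(losses)], losses[1])
})

test_that("checkpoints round-trip bitwise through save and load", {
  m <- buildMSDRCN(small_cfg(), "resnet+ffb", seed = 36)
  x <- array(rnorm(32 * 32 * 2), dim = c(32, 32, 1, 2))
  before <- modelForward(m, x)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- loadCheckpoint(path)
  expect_identical(modelForward(m2, x), before)
  expect_identical(m2$variant, "resnet+ffb")
  expect_error(loadCheckpoint(tempfile()), "not found")
})
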