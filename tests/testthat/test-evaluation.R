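# Confusion-matrix metrics, AUC, and Grad-CAM contracts.

brute_metrics <- function(truth, pred, K) {
  # independent per-sample tally
  n <- length(truth)
  out <- NULL
  for (c in seq_len(K)) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_len(n)) {
      if (truth[i] == c && pred[i] == c) tp <- tp + 1
      if (truth[i] != c && pred[i] == c) fp <- fp + 1
      if (truth[i] == c && pred[i] != c) fn <- fn + 1
      if (truth[i] != c && pred[i] != c) tn <- tn + 1
    }
    out <- rbind(out, c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
  out
}

test_that("confusion matrix equals a per-sample brute-force tally", {
  expect_equal(unname(confusionMatrix(integer(0), integer(0), 3)),
               matrix(0L, 3, 3))
  truth <- rep(1:4, c(3, 2, 1, 4))
  cm <- confusionMatrix(truth, truth, 4)
  expect_equal(diag(cm), c(3, 2, 1, 4))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  set.seed(81)
  t5 <- sample(1:5, 500, TRUE)
  p5 <- sample(1:5, 500, TRUE)
  cm5 <- confusionMatrix(t5, p5, 5)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(cm5[i, j], sum(t5 == i & p5 == j))
  }
  expect_error(confusionMatrix(1:3, 1:2, 3), "equal length")
  expect_error(confusionMatrix(c(1, 6), c(1, 2), 5), "1..K")
})

test_that("per-class metrics reproduce the worked 2x2 example and the oracle", {
  cm <- matrix(c(3, 2, 1, 4), 2, 2)  # rows truth: (3,1),(2,4)
  pc <- perClassMetrics(cm)
  expect_equal(pc$precision[1], 0.6)
  expect_equal(pc$sensitivity[1], 0.75)
  expect_equal(pc$specificity[1], 2 / 3)
  expect_equal(pc$f1[1], 2 * 0.6 * 0.75 / 1.35)
  expect_equal(pc$accuracy[1], 7 / 10)
  # perfect diagonal
  pcd <- perClassMetrics(diag(c(5L, 5L)))
  expect_true(all(unlist(pcd[, -1]) == 1))
  # random matrices against the brute-force tally
  set.seed(82)
  for (r in 1:20) {
    truth <- sample(1:4, 60, TRUE)
    pred <- sample(1:4, 60, TRUE)
    cm <- confusionMatrix(truth, pred, 4)
    bm <- brute_metrics(truth, pred, 4)
    pc <- suppressWarnings(perClassMetrics(cm))
    for (c in 1:4) {
      with_c <- as.list(bm[c, ])
      expect_equal(pc$sensitivity[c], with_c$tp / (with_c$tp + with_c$fn))
      if (with_c$tp + with_c$fp > 0) {
        expect_equal(pc$precision[c], with_c$tp / (with_c$tp + with_c$fp))
      }
      expect_equal(pc$specificity[c], with_c$tn / (with_c$tn + with_c$fp))
      expect_equal(pc$accuracy[c], (with_c$tp + with_c$tn) / 60)
    }
  }
  # zero-prediction convention
  cmz <- matrix(c(0L, 2L, 0L, 1L), 2, 2, byrow = TRUE)  # nobody predicts class 1
  expect_warning(pcz <- perClassMetrics(cmz), "no predictions")
  expect_equal(pcz$precision[1], 0)
  expect_error(perClassMetrics(matrix(0L, 3, 3)), "empty")
})

test_that("overall metrics are trace/N and macro-averages, permutation-invariant", {
  cm <- diag(c(3L, 2L, 1L, 4L))
  cm[1, 2] <- 1L; cm[3, 4] <- 1L
  ov <- overallMetrics(cm)
  expect_equal(ov$oa, 10 / 12)
  expect_equal(overallMetrics(diag(rep(2L, 4)))$oa, 1)
  expect_equal(overallMetrics(diag(rep(2L, 4)))$op, 1)
  set.seed(83)
  for (r in 1:10) {
    cm <- matrix(rpois(16, 5), 4, 4)
    pc <- suppressWarnings(perClassMetrics(cm))
    ov <- suppressWarnings(overallMetrics(cm))
    expect_equal(ov$op, mean(pc$precision))
    expect_equal(ov$macro_f1, mean(pc$f1))
    perm <- sample(4)
    ovp <- suppressWarnings(overallMetrics(cm[perm, perm]))
    expect_equal(ovp$oa, ov$oa)
    expect_equal(ovp$op, ov$op)
  }
})

test_that("one-vs-rest AUC handles separation, inversion, chance, and ties", {
  truth <- rep(1:2, each = 5)
  sc <- cbind(c(seq(0.9, 0.5, length.out = 5), seq(0.4, 0.1, length.out = 5)))
  scores <- cbind(sc, 1 - sc)
  auc <- aucOneVsRest(scores, truth)
  expect_equal(unname(auc), c(1, 1))
  inv <- aucOneVsRest(1 - scores, truth)
  expect_equal(unname(inv), c(0, 0))
  set.seed(84)
  truth <- sample(1:2, 2000, TRUE)
  rnd <- matrix(runif(4000), ncol = 2)
  expect_lt(max(abs(aucOneVsRest(rnd, truth) - 0.5)), 0.05)
  # absent class
  expect_true(is.na(aucOneVsRest(rnd, rep(1, 2000))[2]))
  # cross-check against an established implementation
  skip_if_not_installed("pROC")
  truth <- sample(1:2, 300, TRUE)
  s <- matrix(runif(600), ncol = 2)
  s[truth == 1, 1] <- s[truth == 1, 1] + runif(sum(truth == 1), 0, 0.6)
  ref <- as.numeric(pROC::auc(pROC::roc(truth == 1, s[, 1], quiet = TRUE,
                                        direction = "<")))
  expect_equal(unname(aucOneVsRest(s, truth)[1]), ref, tolerance = 1e-12)
})

test_that("grad-CAM maps are input-sized, normalized, and vanish for constant logits", {
  cfg <- deskConfig(input_size = 32L)
  m <- buildMSDRCN(cfg, "ms-drcn", seed = 85)
  ns <- list(mean = 0.25, std = 0.25)
  img <- generateBScan(phantomSpec("CNV", seed = 86, height = 48, width = 48))$image
  gc <- gradCAM(m, img, ns)
  expect_identical(dim(gc$heatmap), c(32L, 32L))
  expect_true(all(gc$heatmap >= 0 & gc$heatmap <= 1))
  expect_equal(sum(gc$scores), 1)
  # zeroed head: constant logits, zero gradients, all-zero map
  m$head$w$value[] <- 0
  m$head$b$value[] <- 0
  gc0 <- gradCAM(m, img, ns, target_class = "DME")
  expect_true(all(gc0$heatmap == 0))
  expect_error(gradCAM(m, img, ns, layer = "stage9"), "fused1")
  # overlay writer produces a PNG
  p <- tempfile(fileext = ".png")
  writeGradCAMOverlay(img, gc$heatmap, p)
  expect_true(file.exists(p))
})
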