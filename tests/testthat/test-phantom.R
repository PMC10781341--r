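# Phantom generator: determinism, lesion morphology, designed separability.

test_that("rendering is deterministic and masks mark lesions only", {
  s <- phantomSpec("DME", seed = 61)
  b1 <- generateBScan(s)
  b2 <- generateBScan(s)
  expect_identical(b1$image, b2$image)
  expect_identical(b1$mask, b2$mask)
  expect_true(all(b1$image >= 0 & b1$image <= 1))
  expect_gt(sum(b1$mask), 0)
  expect_equal(sum(generateBScan(phantomSpec("Normal", seed = 61))$mask), 0)
  expect_error(phantomSpec("Normal", lesion_params = list(n_cysts = 2)),
               "empty")
  expect_error(generateBScan(phantomSpec("DME", seed = 1,
                                         lesion_params = list(cyst_ry = 500))),
               "larger than image")
})

test_that("DME cysts are hypo-reflective against their surrounding band", {
  gaps <- vapply(1:10, function(i) {
    b <- generateBScan(phantomSpec("DME", seed = 600 + i))
    inside <- mean(b$image[b$mask == 1])
    band <- b$image > 0.25 & b$mask == 0
    inside - mean(b$image[band])
  }, numeric(1))
  expect_true(all(gaps < 0))
})

test_that("dataset generation is checksum-reproducible with the expected layout", {
  root1 <- withr::local_tempdir()
  root2 <- withr::local_tempdir()
  man <- generatePhantomDataset(3, root1, global_seed = 62, height = 64,
                                width = 64)
  generatePhantomDataset(3, root2, global_seed = 62, height = 64, width = 64)
  expect_equal(unname(man$counts), rep(3, 4))
  imgs1 <- list.files(root1, recursive = TRUE, pattern = "png$")
  expect_length(imgs1, 24)  # 12 images + 12 masks
  sums1 <- tools::md5sum(file.path(root1, imgs1))
  sums2 <- tools::md5sum(file.path(root2, imgs1))
  expect_identical(unname(sums1), unname(sums2))
  # masks live in a parallel tree reachable from the image path
  p <- man$records$path[1]
  expect_true(file.exists(phantomMaskPath(p)))
})

test_that("five simple features separate the phantom classes", {
  skip_if_not_installed("randomForest")
  set.seed(63)
  gen <- function(seed0, n) {
    feats <- NULL; y <- NULL; idx <- 0
    for (cl in octClasses()) {
      for (i in seq_len(n)) {
        idx <- idx + 1
        b <- generateBScan(phantomSpec(cl, seed = seed0 + idx))
        feats <- rbind(feats, phantomBaselineFeatures(b$image))
        y <- c(y, cl)
      }
    }
    list(x = as.data.frame(feats), y = factor(y))
  }
  tr <- gen(64000, 40)
  te <- gen(65000, 40)
  rf <- randomForest::randomForest(tr$x, tr$y)
  acc <- mean(predict(rf, te$x) == te$y)
  expect_gt(acc, 0.7)
  # class-conditional effect sizes are non-degenerate: every feature varies
  expect_true(all(vapply(tr$x, sd, numeric(1)) > 0))
})
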