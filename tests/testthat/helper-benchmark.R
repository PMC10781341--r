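# Shared desk-scale benchmark artifacts, built once per test run.
# The phantom benchmark: 250 B-scans per class at 224x224, speckle sigma 0.3,
# split 200 train / 50 validation per class; the compact 64x64 network
# configuration trains on it in a few minutes of CPU time.

.bench <- new.env(parent = emptyenv())

bench_dataset <- function() {
  if (is.null(.bench$man)) {
    root <- file.path(tempdir(), "msdrcn_bench")
    if (!dir.exists(file.path(root, "Normal"))) {
      generatePhantomDataset(250, root, global_seed = 100)
    }
    .bench$man <- scanDataset(root)
    .bench$split <- stratifiedSplit(.bench$man, 0.2, seed = 1)
  }
  list(man = .bench$man, split = .bench$split)
}

bench_trained_full <- function() {
  if (is.null(.bench$fit)) {
    ds <- bench_dataset()
    model <- buildMSDRCN(deskConfig(), "ms-drcn", seed = 1)
    tc <- trainConfig(epochs = 10, batch_size = 32, lr_max = 0.02,
                      lr_min = 1e-4, seed = 1)
    .bench$fit <- trainModel(model, ds$split$train, ds$split$val, tc,
                             verbose = FALSE)
  }
  .bench$fit
}
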