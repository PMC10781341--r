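# Training loop: weighted cross-entropy, SGD with momentum and weight decay,
# cosine-annealed learning rate, best-validation-accuracy checkpointing.

#' Training configuration
#'
#' Defaults follow the published recipe: 50 epochs, batch size 32, SGD with
#' momentum 0.9 and weight decay 1e-4, learning rate cosine-annealed from
#' 1e-3 down to 1e-5, weighted cross-entropy on.
#'
#' @param epochs Number of epochs.
#' @param batch_size Mini-batch size.
#' @param lr_max,lr_min Initial and final learning rate of the cosine
#'   schedule; `0 < lr_min < lr_max`.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param seed Integer seed governing shuffling and augmentation.
#' @param variant Architecture variant (see [modelVariants()]).
#' @param use_class_weights Weight the loss by inverse class frequency.
#' @param augment Apply the augmentation policy during training.
#' @return An object of class `msdrcn_train_config`.
#' @export
trainConfig <- function(epochs = 50L, batch_size = 32L, lr_max = 1e-3,
                        lr_min = 1e-5, momentum = 0.9, weight_decay = 1e-4,
                        seed = 1L, variant = "ms-drcn",
                        use_class_weights = TRUE, augment = TRUE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_min > 0, lr_min < lr_max,
            momentum >= 0, momentum < 1, weight_decay >= 0)
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr_max = lr_max, lr_min = lr_min, momentum = momentum,
              weight_decay = weight_decay, seed = as.integer(seed),
              variant = variant, use_class_weights = isTRUE(use_class_weights),
              augment = isTRUE(augment))
  class(cfg) <- "msdrcn_train_config"
  cfg
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi * t / T)) / 2`, strictly
#' decreasing from `lr_max` at `t = 0` to `lr_min` at `t = T`.
#'
#' @param t Completed-epoch count, `0 <= t <= T`.
#' @param T Total epochs, `T >= 1`.
#' @param lr_max,lr_min Schedule endpoints.
#' @return Learning rate at `t`.
#' @examples
#' cosineLR(0, 50)    # 1e-3
#' cosineLR(50, 50)   # 1e-5
#' @export
cosineLR <- function(t, T, lr_max = 1e-3, lr_min = 1e-5) {
  stopifnot(T >= 1)
  if (any(t < 0 | t > T)) stop("t must lie in [0, T]")
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / T))
}

# Load every image of a manifest, resized to the network input size and
# rescaled to [0, 1]; returns (size, size, 1, N) array plus integer labels.
load_image_stack <- function(manifest, size) {
  n <- nrow(manifest$records)
  x <- array(0, dim = c(size, size, 1L, n))
  for (i in seq_len(n)) {
    img <- readImageGray(manifest$records$path[i])
    if (!all(dim(img) == c(size, size))) img <- resizeBilinear(img, size, size)
    x[, , 1L, i] <- img
  }
  labels <- match(manifest$records$label, manifest$classes)
  list(x = x, labels = labels)
}

standardize_batch <- function(x, stats) (x - stats$mean) / stats$std

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    g <- p$grad + weight_decay * p$value
    p$momentum <- momentum * p$momentum + g
    p$value <- p$value - lr * p$momentum
    p$grad[] <- 0
  }
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

# Evaluation-mode class scores (softmax) for a preloaded image stack.
predict_scores <- function(model, x, stats, batch_size = 32L) {
  n <- dim(x)[4]
  k <- model$config$num_classes
  out <- matrix(0, n, k)
  for (ix in batch_indices(n, batch_size)) {
    xb <- standardize_batch(x[, , , ix, drop = FALSE], stats)
    lg <- modelForward(model, xb, training = FALSE)
    p <- exp(lg - apply(lg, 1, max))
    out[ix, ] <- p / rowSums(p)
  }
  colnames(out) <- model$classes
  out
}

#' Train a network
#'
#' Runs mini-batch SGD with the configured momentum and weight decay; the
#' learning rate is set once per epoch by [cosineLR()]; the loss is
#' cross-entropy weighted by inverse class frequency of the training
#' manifest (uniform if disabled). Validation loss/accuracy are computed
#' each epoch in evaluation mode and the parameter state with the best
#' validation accuracy (ties broken by earliest epoch) is restored into the
#' returned model.
#'
#' @param model A model from [buildMSDRCN()] (its variant should match
#'   `config$variant`).
#' @param train_manifest,val_manifest Dataset manifests.
#' @param config A [trainConfig()].
#' @param policy Augmentation policy applied to training images.
#' @param norm_stats Normalization statistics (`list(mean, std)`); computed
#'   from the training images when `NULL`.
#' @param checkpoint_path If non-`NULL`, the best checkpoint is also written
#'   here via [saveCheckpoint()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best state restored), `history` (per-epoch data
#'   frame), `best_epoch`, and `norm_stats`.
#' @export
trainModel <- function(model, train_manifest, val_manifest, config,
                       policy = augmentationPolicy(), norm_stats = NULL,
                       checkpoint_path = NULL, verbose = TRUE) {
  if (nrow(train_manifest$records) == 0 || nrow(val_manifest$records) == 0) {
    stop("train and validation manifests must be non-empty")
  }
  size <- model$config$input_size
  tr <- load_image_stack(train_manifest, size)
  va <- load_image_stack(val_manifest, size)
  if (is.null(norm_stats)) {
    m <- mean(tr$x)
    norm_stats <- list(mean = m, std = max(sd(as.numeric(tr$x)), 1e-6))
  }
  counts <- vapply(seq_along(train_manifest$classes), function(k) {
    sum(tr$labels == k)
  }, numeric(1))
  if (any(counts == 0)) stop("every class needs at least one training image")
  weights <- if (config$use_class_weights) classWeights(counts) else rep(1, length(counts))
  params <- collect_params(model)
  n <- length(tr$labels)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), train_acc = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  best <- list(acc = -Inf, epoch = NA_integer_, state = NULL)
  for (epoch in seq_len(config$epochs)) {
    lr <- cosineLR(epoch - 1L, config$epochs, config$lr_max, config$lr_min)
    set.seed(config$seed + 7919L * epoch)
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0; ep_correct <- 0
    for (ix in batch_indices(n, config$batch_size)) {
      ids <- ord[ix]
      xb <- array(0, dim = c(size, size, 1L, length(ids)))
      for (j in seq_along(ids)) {
        img <- tr$x[, , 1L, ids[j]]
        if (config$augment) {
          img <- augmentImage(img, policy,
                              seed = config$seed + 104729L * epoch + ids[j])
        }
        xb[, , 1L, j] <- img
      }
      xb <- standardize_batch(xb, norm_stats)
      yb <- tr$labels[ids]
      ad_tape_begin()
      out <- model_forward_nodes(model, ad_input(xb), training = TRUE)
      loss <- op_wce(out$logits, yb, weights)
      lv <- ad_val(loss)
      if (!is.finite(lv)) {
        ad_tape_end()
        stop("non-finite training loss at epoch ", epoch,
             " (learning rate ", signif(lr, 3), "); aborting")
      }
      ad_backward(loss)
      ad_tape_end()
      sgd_step(params, lr, config$momentum, config$weight_decay)
      pred <- apply(ad_val(out$logits), 2, which.max)
      ep_correct <- ep_correct + sum(pred == yb)
      ep_loss <- ep_loss + lv * length(ids)
      ep_n <- ep_n + length(ids)
    }
    vs <- predict_scores(model, va$x, norm_stats, config$batch_size)
    vpred <- apply(vs, 1, which.max)
    val_acc <- mean(vpred == va$labels)
    val_loss <- -mean(log(pmax(vs[cbind(seq_along(va$labels), va$labels)], 1e-12)))
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss / ep_n,
                                   train_acc = ep_correct / ep_n,
                                   val_loss = val_loss, val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %2d  lr %.2e  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                      epoch, lr, ep_loss / ep_n, ep_correct / ep_n,
                      val_loss, val_acc))
    }
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch, state = collect_state(model))
    }
  }
  restore_state(model, best$state)
  if (!is.null(checkpoint_path)) saveCheckpoint(model, checkpoint_path)
  list(model = model, history = hist, best_epoch = best$epoch,
       norm_stats = norm_stats)
}

#' Predict class scores for a manifest
#'
#' @param model A trained model.
#' @param manifest Dataset manifest.
#' @param norm_stats Normalization statistics used during training.
#' @param batch_size Inference batch size.
#' @return List with `scores` (N x K softmax matrix), `pred` (integer class
#'   indices), and `labels` (integer truth from the manifest).
#' @export
predictManifest <- function(model, manifest, norm_stats, batch_size = 32L) {
  st <- load_image_stack(manifest, model$config$input_size)
  scores <- predict_scores(model, st$x, norm_stats, batch_size)
  list(scores = scores, pred = apply(scores, 1, which.max),
       labels = st$labels)
}
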