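# Confusion-matrix metrics, one-vs-rest AUC, and the PSNR robustness sweep.

#' Multi-class confusion matrix
#'
#' @param truth,pred Integer class indices in `1..K` (or factors/characters
#'   matched against `classes`).
#' @param K Number of classes.
#' @param classes Optional class names for the dimnames.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusionMatrix <- function(truth, pred, K, classes = NULL) {
  if (!is.null(classes)) {
    if (is.character(truth) || is.factor(truth)) truth <- match(as.character(truth), classes)
    if (is.character(pred) || is.factor(pred)) pred <- match(as.character(pred), classes)
  }
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  if (length(truth) > 0 &&
      (any(truth < 1 | truth > K) || any(pred < 1 | pred > K))) {
    stop("labels must lie in 1..K")
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth)) {
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  }
  if (!is.null(classes)) dimnames(cm) <- list(truth = classes, pred = classes)
  cm
}

#' Per-class one-vs-rest metrics
#'
#' For each class c: `TP = cm[c,c]`, `FP` = column sum minus TP, `FN` = row
#' sum minus TP, `TN = N - TP - FP - FN`; then accuracy `(TP+TN)/N`,
#' precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F1 the harmonic mean of precision and sensitivity.
#' When a class has no predicted and no true positives, precision and F1 are
#' reported as 0 with a warning.
#'
#' @param cm Confusion matrix from [confusionMatrix()].
#' @return Data frame with one row per class.
#' @export
perClassMetrics <- function(cm) {
  n <- sum(cm)
  if (n < 1) stop("confusion matrix is empty")
  K <- nrow(cm)
  out <- data.frame(class = if (!is.null(rownames(cm))) rownames(cm) else seq_len(K),
                    accuracy = NA_real_, precision = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    f1 = NA_real_)
  for (c in seq_len(K)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) {
      warning("class ", out$class[c], " received no predictions; precision set to 0")
      0
    } else tp / (tp + fp)
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(sens) || prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    out$accuracy[c] <- (tp + tn) / n
    out$precision[c] <- prec
    out$sensitivity[c] <- sens
    out$specificity[c] <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    out$f1[c] <- f1
  }
  out
}

#' Overall accuracy, overall (macro) precision, macro F1
#'
#' `OA = trace(cm)/N`; `OP` is the unweighted mean of per-class precisions;
#' macro-F1 the unweighted mean of per-class F1 scores.
#'
#' @param cm Confusion matrix.
#' @return Named list with `oa`, `op`, `macro_f1`.
#' @export
overallMetrics <- function(cm) {
  pc <- perClassMetrics(cm)
  list(oa = sum(diag(cm)) / sum(cm), op = mean(pc$precision),
       macro_f1 = mean(pc$f1))
}

#' One-vs-rest AUC with midrank tie handling
#'
#' For each class, ranks that class's score column against the binary
#' one-vs-rest truth (Mann-Whitney formulation, equivalent to the
#' trapezoidal ROC area with midranks for ties). Classes absent from the
#' truth get `NA`.
#'
#' @param scores N x K matrix of class scores.
#' @param truth Integer class indices in `1..K`.
#' @return Numeric vector of K AUCs.
#' @export
aucOneVsRest <- function(scores, truth) {
  stopifnot(all(is.finite(scores)))
  K <- ncol(scores)
  out <- rep(NA_real_, K)
  names(out) <- colnames(scores)
  for (c in seq_len(K)) {
    pos <- truth == c
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    r <- rank(scores[, c], ties.method = "average")
    out[c] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

#' Full metric report for a prediction run
#'
#' @param truth,pred Integer class indices.
#' @param scores Optional N x K score matrix for AUC.
#' @param classes Class vocabulary.
#' @return List of class `msdrcn_metrics` with the confusion matrix,
#'   per-class table, overall metrics and optional per-class AUC.
#' @export
metricReport <- function(truth, pred, scores = NULL, classes = octClasses()) {
  cm <- confusionMatrix(truth, pred, length(classes), classes)
  rep <- list(confusion = cm, per_class = perClassMetrics(cm),
              overall = overallMetrics(cm),
              auc = if (!is.null(scores)) aucOneVsRest(scores, truth) else NULL)
  class(rep) <- "msdrcn_metrics"
  rep
}

#' @export
print.msdrcn_metrics <- function(x, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\nPer-class metrics:\n")
  print(x$per_class, digits = 3)
  cat(sprintf("\nOA %.3f  OP %.3f  macro-F1 %.3f\n",
              x$overall$oa, x$overall$op, x$overall$macro_f1))
  if (!is.null(x$auc)) {
    cat("AUC:", paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = "  "), "\n")
  }
  invisible(x)
}

#' PSNR robustness sweep
#'
#' Re-evaluates a trained model on a test manifest whose images are
#' corrupted at each requested PSNR level (in the stored 8-bit domain,
#' before the standard preprocessing), reporting overall accuracy per
#' level. `Inf` in `psnr_levels` evaluates the clean images.
#'
#' @param model A trained model.
#' @param manifest Test manifest.
#' @param norm_stats Normalization statistics used during training.
#' @param noise_kind `"gaussian"` or `"speckle"`.
#' @param psnr_levels PSNR targets in dB (default the published sweep
#'   35/32/29/26/23/20).
#' @param seed Base corruption seed.
#' @param batch_size Inference batch size.
#' @return Data frame with `noise_kind`, `psnr_db`, `oa`, and the mean
#'   achieved PSNR per level.
#' @export
robustnessSweep <- function(model, manifest, norm_stats,
                            noise_kind = c("gaussian", "speckle"),
                            psnr_levels = c(35, 32, 29, 26, 23, 20),
                            seed = 1L, batch_size = 32L) {
  noise_kind <- match.arg(noise_kind)
  size <- model$config$input_size
  n <- nrow(manifest$records)
  if (n == 0) stop("empty test manifest")
  labels <- match(manifest$records$label, manifest$classes)
  raw <- lapply(manifest$records$path, function(p) readImageGray(p) * 255)
  out <- data.frame()
  for (lvl in psnr_levels) {
    x <- array(0, dim = c(size, size, 1L, n))
    achieved <- numeric(n)
    for (i in seq_len(n)) {
      f <- if (is.infinite(lvl)) raw[[i]] else {
        switch(noise_kind,
               gaussian = addGaussianNoise(raw[[i]], lvl, 255, seed + i),
               speckle = addSpeckleNoise(raw[[i]], lvl, 255, seed + i))
      }
      achieved[i] <- psnr(raw[[i]], f, 255)
      x[, , 1L, i] <- preprocessImage(f, size, mean = 0, std = 1, max_val = 255)
    }
    scores <- predict_scores(model, standardize_batch(x, norm_stats),
                             list(mean = 0, std = 1), batch_size)
    oa <- mean(apply(scores, 1, which.max) == labels)
    out <- rbind(out, data.frame(noise_kind = noise_kind, psnr_db = lvl,
                                 oa = oa,
                                 achieved_db = mean(achieved[is.finite(achieved)])))
  }
  out
}
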