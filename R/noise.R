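# PSNR computation and PSNR-calibrated image corruption.
#
# The OCT speckle model is multiplicative: f = x * m with m ~ Normal(1, s^2)
# i.i.d.; additive detector noise is negligible against it and is dropped.
# Both corruptions are calibrated analytically so that the *expected* mean
# squared error equals (max_val * 10^(-psnr/20))^2, i.e. the expected PSNR
# equals the requested target. No clipping is applied during corruption
# (clipping would bias the achieved PSNR above target); values are clamped
# only when exporting to 8-bit files.

#' Peak signal-to-noise ratio
#'
#' `20 * log10(max_val / sqrt(MSE))` in decibels, `Inf` for identical images.
#'
#' @param reference,test Numeric arrays of identical shape.
#' @param max_val Maximum representable pixel value (255 for 8-bit images,
#'   1 for normalized images).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(0.1, 4, 4), max_val = 1)  # 20 dB
#' @export
psnr <- function(reference, test, max_val = 255) {
  if (!identical(dim_or_len(reference), dim_or_len(test))) {
    stop("reference and test images must have identical shapes")
  }
  stopifnot(max_val > 0)
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  20 * log10(max_val / sqrt(mse))
}

#' Add PSNR-calibrated Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `max_val * 10^(-target_psnr/20)`, so the expected PSNR of the corrupted
#' image against the original equals `target_psnr`. The output is not
#' clipped.
#'
#' @param image Numeric matrix/array of pixel intensities.
#' @param target_psnr Target PSNR in dB; `Inf` returns the image unchanged.
#' @param max_val Maximum representable pixel value.
#' @param seed Integer seed; the corruption is deterministic given the seed.
#' @return Corrupted image, same shape.
#' @export
addGaussianNoise <- function(image, target_psnr, max_val = 255, seed = 1L) {
  stopifnot(max_val > 0)
  if (is.infinite(target_psnr) && target_psnr > 0) return(image)
  sigma <- max_val * 10^(-target_psnr / 20)
  set.seed(as.integer(seed))
  image + array(rnorm(length(image), sd = sigma), dim = dim_or_len(image))
}

#' Add PSNR-calibrated multiplicative speckle noise
#'
#' Applies `f = x * m` with `m ~ Normal(1, s^2)` i.i.d., where
#' `s = max_val * 10^(-target_psnr/20) / rms(x)`. The expected mean squared
#' error is then `s^2 * mean(x^2)`, so the expected PSNR equals the target.
#'
#' @inheritParams addGaussianNoise
#' @return Corrupted image, same shape.
#' @export
addSpeckleNoise <- function(image, target_psnr, max_val = 255, seed = 1L) {
  stopifnot(max_val > 0)
  rms <- sqrt(mean(as.numeric(image)^2))
  if (rms == 0) {
    stop("speckle strength is undefined for an all-zero image")
  }
  if (is.infinite(target_psnr) && target_psnr > 0) return(image)
  sigma_m <- max_val * 10^(-target_psnr / 20) / rms
  set.seed(as.integer(seed))
  image * (1 + array(rnorm(length(image), sd = sigma_m), dim = dim_or_len(image)))
}

#' Corrupt a test set at a calibrated PSNR
#'
#' Applies Gaussian or speckle corruption to every image of a manifest in the
#' stored 8-bit intensity domain (before any resizing or normalization),
#' using per-image seeds `seed + index`, and logs the achieved PSNR per
#' image. Optionally writes the corrupted images (clamped to `[0, max_val]`
#' only at export) as a PNG tree mirroring the class layout.
#'
#' @param manifest A dataset manifest from [scanDataset()].
#' @param noise_kind `"gaussian"` or `"speckle"`.
#' @param target_psnr Target PSNR in dB.
#' @param seed Base integer seed.
#' @param out_dir If non-`NULL`, directory where the corrupted image tree is
#'   written.
#' @param keep_images Return the corrupted arrays in memory.
#' @param max_val Intensity ceiling of the stored images (default 255).
#' @return List with `log` (data frame: path, label, target_db, achieved_db)
#'   and, if `keep_images`, `images` (list of corrupted arrays, pre-clip).
#' @export
corruptTestSet <- function(manifest, noise_kind = c("gaussian", "speckle"),
                           target_psnr, seed = 1L, out_dir = NULL,
                           keep_images = TRUE, max_val = 255) {
  noise_kind <- match.arg(noise_kind)
  recs <- manifest$records
  n <- nrow(recs)
  achieved <- numeric(n)
  images <- if (keep_images) vector("list", n) else NULL
  for (i in seq_len(n)) {
    x <- readImageGray(recs$path[i]) * max_val
    f <- switch(noise_kind,
                gaussian = addGaussianNoise(x, target_psnr, max_val, seed + i),
                speckle = addSpeckleNoise(x, target_psnr, max_val, seed + i))
    achieved[i] <- psnr(x, f, max_val)
    if (keep_images) images[[i]] <- f
    if (!is.null(out_dir)) {
      dst <- file.path(out_dir, recs$label[i],
                       sprintf("%s_%s_%gdB.png",
                               tools::file_path_sans_ext(basename(recs$path[i])),
                               noise_kind, target_psnr))
      dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
      png::writePNG(pmin(pmax(f / max_val, 0), 1), dst)
    }
  }
  log <- data.frame(path = recs$path, label = recs$label,
                    target_db = rep(target_psnr, n), achieved_db = achieved,
                    stringsAsFactors = FALSE)
  out <- list(log = log)
  if (keep_images) out$images <- images
  out
}
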