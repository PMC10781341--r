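# Dataset discovery, preprocessing, augmentation, class weighting and
# stratified splitting. Images are H x W matrices of intensities in [0, 1]
# (EBImage handles decoding; color images are averaged to grayscale).

IMAGE_EXT <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Default retinal OCT class vocabulary
#' @return `c("CNV", "DME", "Drusen", "Normal")`
#' @export
octClasses <- function() c("CNV", "DME", "Drusen", "Normal")

#' Scan a class-per-directory image tree
#'
#' Expects `root` to contain one subdirectory per class (the layout of the
#' public retinal OCT archives) and lists all PNG/JPEG/TIFF files in stable
#' lexicographic order. Non-image files are skipped with a message.
#'
#' @param root Dataset root directory.
#' @param classes Ordered class vocabulary; each must exist as a
#'   subdirectory.
#' @return An object of class `msdrcn_manifest`: list with `records` (data
#'   frame of `path`, `label`), `classes`, and per-class `counts`.
#' @export
scanDataset <- function(root, classes = octClasses()) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  missing <- classes[!dir.exists(file.path(root, classes))]
  if (length(missing) > 0) {
    stop("missing class directories under ", root, ": ",
         paste(missing, collapse = ", "))
  }
  paths <- character(0)
  labels <- character(0)
  for (cl in classes) {
    fs <- list.files(file.path(root, cl), recursive = TRUE, full.names = TRUE)
    fs <- sort(fs, method = "radix")
    is_img <- tolower(tools::file_ext(fs)) %in% IMAGE_EXT
    if (any(!is_img)) {
      message("skipping ", sum(!is_img), " non-image file(s) in class ", cl)
    }
    fs <- fs[is_img]
    paths <- c(paths, fs)
    labels <- c(labels, rep(cl, length(fs)))
  }
  if (length(paths) == 0) stop("no image files found under ", root)
  new_manifest(data.frame(path = paths, label = labels,
                          stringsAsFactors = FALSE), classes)
}

new_manifest <- function(records, classes) {
  counts <- vapply(classes, function(cl) sum(records$label == cl), numeric(1))
  m <- list(records = records, classes = classes, counts = counts)
  class(m) <- "msdrcn_manifest"
  m
}

#' @export
print.msdrcn_manifest <- function(x, ...) {
  cat("Dataset manifest:", nrow(x$records), "images\n")
  for (cl in x$classes) cat("  ", cl, ": ", x$counts[[cl]], "\n", sep = "")
  invisible(x)
}

#' Write / read a manifest as CSV
#' @param manifest A manifest from [scanDataset()].
#' @param path CSV file path.
#' @return `path` (write) or a manifest (read).
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @param classes Class vocabulary for the loaded manifest.
#' @export
readManifest <- function(path, classes = octClasses()) {
  recs <- read.csv(path, stringsAsFactors = FALSE)
  new_manifest(recs, classes)
}

#' Read an image as a grayscale intensity matrix
#'
#' @param path Image file (PNG/JPEG/TIFF).
#' @return H x W matrix with intensities in `[0, 1]`.
#' @export
readImageGray <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image ", path, ": ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 3) {
    img <- apply(img, c(1, 2), mean)
  }
  t(as.matrix(img))  # EBImage stores (x, y); transpose to (row, col)
}

#' Preprocess an image for the network
#'
#' Bilinear resize to `size` x `size`, rescale to `[0, 1]` by `max_val`, then
#' standardize: `(x/max_val - mean) / std`.
#'
#' @param image H x W numeric matrix.
#' @param size Target side length.
#' @param mean,std Normalization statistics in the `[0, 1]` intensity domain
#'   (see [computeNormalizationStats()]).
#' @param max_val Intensity ceiling of `image` (1 for already-normalized
#'   matrices, 255 for 8-bit intensities).
#' @return `(size, size, 1)` array.
#' @export
preprocessImage <- function(image, size = 224L, mean = 0, std = 1,
                            max_val = 1) {
  stopifnot(std > 0, max_val > 0)
  x <- image / max_val
  if (!all(dim(x) == c(size, size))) {
    x <- resizeBilinear(x, size, size)
  }
  x <- (x - mean) / std
  array(x, dim = c(size, size, 1L))
}

resizeBilinear <- function(image, h, w) {
  t(as.matrix(EBImage::resize(t(image), w = w, h = h, filter = "bilinear")))
}

#' Mean/SD normalization statistics of a training set
#'
#' @param manifest A manifest from [scanDataset()].
#' @return List with `mean` and `std` of all pixel intensities in `[0, 1]`.
#' @export
computeNormalizationStats <- function(manifest) {
  s <- 0; s2 <- 0; n <- 0
  for (p in manifest$records$path) {
    x <- readImageGray(p)
    s <- s + sum(x); s2 <- s2 + sum(x^2); n <- n + length(x)
  }
  m <- s / n
  list(mean = m, std = sqrt(max(s2 / n - m^2, 1e-12)))
}

#' Augmentation policy
#'
#' Symmetric augmentation ranges: rotation `±rotation_deg` degrees, isotropic
#' scale `1 ± scale_frac`, brightness multiplier `1 ± brightness_frac`,
#' horizontal flip with probability `hflip_prob`.
#'
#' @param rotation_deg Rotation half-range in degrees (default 15).
#' @param scale_frac Scale half-range (default 0.20).
#' @param brightness_frac Brightness half-range (default 0.20).
#' @param hflip Enable horizontal flipping.
#' @param hflip_prob Flip probability when enabled.
#' @return An object of class `msdrcn_policy`.
#' @export
augmentationPolicy <- function(rotation_deg = 15, scale_frac = 0.20,
                               brightness_frac = 0.20, hflip = TRUE,
                               hflip_prob = 0.5) {
  stopifnot(rotation_deg >= 0, scale_frac >= 0, brightness_frac >= 0,
            hflip_prob >= 0, hflip_prob <= 1)
  p <- list(rotation_deg = rotation_deg, scale_frac = scale_frac,
            brightness_frac = brightness_frac, hflip = isTRUE(hflip),
            hflip_prob = hflip_prob)
  class(p) <- "msdrcn_policy"
  p
}

# Center-fixed rotation + isotropic scaling via a single bilinear warp.
warp_rotate_scale <- function(image, angle_deg, scale) {
  if (angle_deg == 0 && scale == 1) return(image)
  H <- nrow(image); W <- ncol(image)
  th <- angle_deg * pi / 180
  A <- scale * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  off <- c(cx, cy) - A %*% c(cx, cy)
  m <- rbind(t(A), as.numeric(off))
  out <- EBImage::affine(t(image), m, filter = "bilinear",
                         output.dim = c(W, H), bg.col = 0)
  t(as.matrix(out))
}

#' Apply a random augmentation
#'
#' Samples rotation, scale, brightness and flip from the policy ranges and
#' applies them in the fixed order rotate, scale, brightness, flip.
#' Deterministic given `seed`.
#'
#' @param image H x W matrix in `[0, 1]`.
#' @param policy An [augmentationPolicy()].
#' @param seed Integer seed.
#' @return Augmented H x W matrix.
#' @export
augmentImage <- function(image, policy = augmentationPolicy(), seed = 1L) {
  set.seed(as.integer(seed))
  angle <- runif(1, -policy$rotation_deg, policy$rotation_deg)
  scale <- 1 + runif(1, -policy$scale_frac, policy$scale_frac)
  bright <- 1 + runif(1, -policy$brightness_frac, policy$brightness_frac)
  flip <- policy$hflip && runif(1) < policy$hflip_prob
  x <- warp_rotate_scale(image, angle, scale)
  x <- pmin(pmax(x * bright, 0), 1)
  if (flip) x <- x[, ncol(x):1, drop = FALSE]
  x
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)`: a mean-weighted sample contributes weight 1, so a
#' perfectly balanced set yields uniform unit weights and the weighted
#' cross-entropy reduces to the unweighted loss.
#'
#' @param counts Named or unnamed vector of positive per-class counts.
#' @return Per-class positive weights.
#' @examples
#' classWeights(c(10, 10, 10, 10))  # all 1
#' @export
classWeights <- function(counts) {
  if (any(counts <= 0)) stop("all class counts must be positive")
  n <- sum(counts)
  k <- length(counts)
  n / (k * counts)
}

#' Stratified train/validation split
#'
#' Randomly assigns `round(n_c * val_fraction)` members of each class (at
#' least 1 when the class has at least 2 members) to validation; the split is
#' disjoint, exhaustive, and deterministic given `seed`.
#'
#' @param manifest A manifest from [scanDataset()].
#' @param val_fraction Validation fraction in (0, 1) (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `val` manifests.
#' @export
stratifiedSplit <- function(manifest, val_fraction = 0.2, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  set.seed(as.integer(seed))
  recs <- manifest$records
  val_idx <- integer(0)
  for (cl in manifest$classes) {
    idx <- which(recs$label == cl)
    n <- length(idx)
    if (n == 0) next
    nv <- round(n * val_fraction)
    if (n >= 2) nv <- max(nv, 1L)
    if (n == 1 && val_fraction >= 0.5) {
      warning("class ", cl, " has a single member; keeping it in train")
      nv <- 0L
    }
    nv <- min(nv, n - 1L)
    if (nv > 0) val_idx <- c(val_idx, sample(idx, nv))
  }
  list(
    train = new_manifest(recs[setdiff(seq_len(nrow(recs)), val_idx), ,
                              drop = FALSE], manifest$classes),
    val = new_manifest(recs[sort(val_idx), , drop = FALSE], manifest$classes)
  )
}
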