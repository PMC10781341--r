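# Synthetic retinal B-scan phantoms.
#
# A phantom is a stack of smoothly curved reflective bands (the retinal
# strata) over a dark background, plus class-specific lesion morphology:
# Drusen get small dome-shaped elevations of the bright outer band, DME gets
# round hypo-reflective intraretinal cysts and a thickened band, CNV gets a
# larger sub-band fluid pocket adjacent to a hyper-reflective fibrotic scar
# blob, and Normal gets none. Multiplicative speckle (x * m, m ~ N(1, s^2))
# is applied last. Geometry is deliberately low-dimensional so that lesions,
# not texture, carry the class signal.

#' Phantom B-scan specification
#'
#' @param class_label One of `"CNV"`, `"DME"`, `"Drusen"`, `"Normal"`.
#' @param height,width Image size in pixels (defaults 224 x 224).
#' @param layer_count Number of retinal bands rendered (default 6).
#' @param curvature Amplitude of the low-frequency bending of the band stack,
#'   as a fraction of the image height (default 0.05).
#' @param lesion_params Optional named list overriding the class defaults
#'   (Drusen: `n_bumps`, `bump_width`, `bump_height`; DME: `n_cysts`,
#'   `cyst_rx`, `cyst_ry`, `thicken`; CNV: `pocket_rx`, `pocket_ry`,
#'   `scar_rx`, `scar_ry`). Must be empty for Normal.
#' @param speckle_sigma Standard deviation of the multiplicative speckle
#'   multiplier (default 0.3).
#' @param seed Integer seed; rendering is deterministic given the spec.
#' @return An object of class `msdrcn_phantom_spec`.
#' @export
phantomSpec <- function(class_label, height = 224L, width = 224L,
                        layer_count = 6L, curvature = 0.05,
                        lesion_params = list(), speckle_sigma = 0.3,
                        seed = 1L) {
  class_label <- match.arg(class_label, octClasses())
  stopifnot(height >= 32, width >= 32, layer_count >= 2, speckle_sigma >= 0)
  if (class_label == "Normal" && length(lesion_params) > 0) {
    stop("lesion_params must be empty for Normal phantoms")
  }
  s <- list(class_label = class_label, height = as.integer(height),
            width = as.integer(width), layer_count = as.integer(layer_count),
            curvature = curvature, lesion_params = lesion_params,
            speckle_sigma = speckle_sigma, seed = as.integer(seed))
  class(s) <- "msdrcn_phantom_spec"
  s
}

# Default lesion parameter ranges, scaled to the image size.
phantom_lesion_defaults <- function(class_label, H, W) {
  sc <- min(H, W) / 224
  switch(class_label,
    Drusen = list(n_bumps = c(3L, 7L), bump_width = c(8, 18) * sc,
                  bump_height = c(8, 18) * sc),
    DME = list(n_cysts = c(2L, 4L), cyst_rx = c(10, 22) * sc,
               cyst_ry = c(6, 12) * sc, thicken = 1.35),
    CNV = list(pocket_rx = c(22, 35) * sc, pocket_ry = c(10, 18) * sc,
               scar_rx = c(10, 18) * sc, scar_ry = c(6, 12) * sc),
    Normal = list()
  )
}

runif1 <- function(range) if (length(range) == 2) runif(1, range[1], range[2]) else range
rint1 <- function(range) if (length(range) == 2) sample(seq(range[1], range[2]), 1) else range

# Filled ellipse mask, clipped to the image.
ellipse_mask <- function(H, W, cy, cx, ry, rx) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
}

#' Render a synthetic B-scan phantom
#'
#' @param spec A [phantomSpec()].
#' @return List with `image` (H x W matrix in `[0, 1]`, speckled) and `mask`
#'   (binary H x W lesion mask; all zero for Normal).
#' @export
generateBScan <- function(spec) {
  stopifnot(inherits(spec, "msdrcn_phantom_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  lp <- phantom_lesion_defaults(spec$class_label, H, W)
  lp[names(spec$lesion_params)] <- spec$lesion_params

  # band geometry: low-order sinusoid top boundary, near-constant thickness
  u <- seq(0, 1, length.out = W)
  freq <- runif(1, 0.6, 1.4)
  phase <- runif(1, 0, 2 * pi)
  slope <- runif(1, -0.04, 0.04)
  ytop <- H * (0.34 + spec$curvature * sin(2 * pi * freq * u + phase) +
                 slope * (u - 0.5))
  th <- H * 0.22 * runif(1, 0.9, 1.1)
  if (spec$class_label == "DME") th <- th * (if (!is.null(lp$thicken)) lp$thicken else 1.35)
  ybot <- ytop + th

  # per-band reflectivities, brightest outer band (RPE-like)
  nl <- spec$layer_count
  base_refl <- seq(0.65, 0.4, length.out = max(nl - 1, 1))
  base_refl[seq(2, length(base_refl), by = 2)] <-
    base_refl[seq(2, length(base_refl), by = 2)] - 0.18
  refl <- pmin(pmax(c(base_refl, 0.85) + runif(nl, -0.04, 0.04), 0.05), 1)
  fracs <- seq(0, 1, length.out = nl + 1)

  rr <- matrix(seq_len(H), H, W)
  ytop_m <- matrix(ytop, H, W, byrow = TRUE)
  depth <- (rr - ytop_m) / th
  img <- matrix(0.04, H, W)
  band <- findInterval(pmin(pmax(depth, 0), 0.999999), fracs)
  inside <- depth >= 0 & depth < 1
  img[inside] <- refl[band[inside]]
  below <- depth >= 1 & depth < 1.35
  img[below] <- 0.15

  mask <- matrix(FALSE, H, W)
  ybot_m <- ytop_m + th

  if (spec$class_label == "Drusen") {
    nb <- rint1(lp$n_bumps)
    xs <- sort(runif(nb, 0.1 * W, 0.9 * W))
    for (x0 in xs) {
      wd <- runif1(lp$bump_width)
      hb <- runif1(lp$bump_height)
      if (hb >= H || wd >= W) stop("lesion larger than image")
      cc <- matrix(seq_len(W), H, W, byrow = TRUE)
      dome <- hb * exp(-((cc - x0) / (wd / 2))^2)
      sel <- rr >= ybot_m - 0.1 * th - dome & rr <= ybot_m - 0.1 * th & dome > 0.5
      img[sel] <- 0.85
      mask <- mask | sel
    }
  } else if (spec$class_label == "DME") {
    nc <- rint1(lp$n_cysts)
    for (i in seq_len(nc)) {
      rx <- runif1(lp$cyst_rx); ry <- runif1(lp$cyst_ry)
      if (2 * ry >= H || 2 * rx >= W) stop("lesion larger than image")
      cx <- runif(1, rx + 2, W - rx - 2)
      dfrac <- runif(1, 0.3, 0.7)
      cy <- ytop[max(1L, min(W, round(cx)))] + dfrac * th
      sel <- ellipse_mask(H, W, cy, cx, ry, rx) & inside
      img[sel] <- 0.1
      mask <- mask | sel
    }
  } else if (spec$class_label == "CNV") {
    prx <- runif1(lp$pocket_rx); pry <- runif1(lp$pocket_ry)
    srx <- runif1(lp$scar_rx); sry <- runif1(lp$scar_ry)
    if (2 * pry >= H || 2 * prx >= W) stop("lesion larger than image")
    cx <- runif(1, prx + srx + 4, W - prx - srx - 4)
    cy <- ytop[max(1L, min(W, round(cx)))] + 0.8 * th
    pocket <- ellipse_mask(H, W, cy, cx, pry, prx)
    img[pocket] <- 0.08
    side <- sample(c(-1, 1), 1)
    scx <- cx + side * (prx * 0.8 + srx * 0.6)
    scar <- ellipse_mask(H, W, cy + 0.2 * pry, scx, sry, srx)
    img[scar] <- 0.9
    mask <- pocket | scar
  }

  if (spec$speckle_sigma > 0) {
    img <- img * (1 + matrix(rnorm(H * W, sd = spec$speckle_sigma), H, W))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask * 1)
}

#' Generate a labelled phantom dataset on disk
#'
#' Writes `n_per_class` 8-bit grayscale PNG phantoms per class into
#' class-per-directory layout under `root`, with binary lesion masks in a
#' parallel `masks/` tree, and returns the dataset manifest. Per-image seeds
#' are `global_seed + running index`, so the dataset is bit-reproducible.
#'
#' @param n_per_class Images per class.
#' @param root Output directory (created if needed).
#' @param global_seed Base integer seed.
#' @param speckle_sigma Speckle level passed to every [phantomSpec()].
#' @param height,width Image size.
#' @param classes Class vocabulary to generate.
#' @return The dataset manifest (see [scanDataset()]).
#' @export
generatePhantomDataset <- function(n_per_class, root, global_seed = 1L,
                                   speckle_sigma = 0.3, height = 224L,
                                   width = 224L, classes = octClasses()) {
  stopifnot(n_per_class >= 1)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create output directory ", root)
  idx <- 0L
  for (cl in classes) {
    dir.create(file.path(root, cl), showWarnings = FALSE)
    dir.create(file.path(root, "masks", cl), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      spec <- phantomSpec(cl, height = height, width = width,
                          speckle_sigma = speckle_sigma,
                          seed = global_seed + idx)
      bs <- generateBScan(spec)
      name <- sprintf("%s_%04d.png", tolower(cl), i)
      png::writePNG(bs$image, file.path(root, cl, name))
      png::writePNG(bs$mask, file.path(root, "masks", cl, name))
    }
  }
  scanDataset(root, classes)
}

#' Mask path for a phantom image path
#' @param path Image path inside a phantom dataset tree.
#' @return The corresponding mask path in the parallel `masks/` tree.
#' @export
phantomMaskPath <- function(path) {
  file.path(dirname(dirname(path)), "masks", basename(dirname(path)),
            basename(path))
}

#' Simple interpretable features of a B-scan
#'
#' Five summary features used as a designed-separability baseline for the
#' phantom classes: mean retinal band thickness (pixels), count of dark
#' blobs inside the band (cysts/fluid), bright-blob area fraction
#' (scar/deposits), bump count of the outer band boundary (drusen), and the
#' overall intensity variance.
#'
#' @param image H x W matrix in `[0, 1]`.
#' @return Named numeric vector of 5 features.
#' @export
phantomBaselineFeatures <- function(image) {
  sm <- t(as.matrix(EBImage::gblur(t(image), sigma = 1.5)))
  H <- nrow(sm); W <- ncol(sm)
  bright <- sm > 0.25
  thickness <- mean(colSums(bright))
  # band extent per column
  bot <- apply(sm > 0.45, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) NA_real_ else max(w)
  })
  top <- apply(bright, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) NA_real_ else min(w)
  })
  inband <- matrix(FALSE, H, W)
  for (j in seq_len(W)) {
    if (!is.na(top[j]) && !is.na(bot[j]) && bot[j] > top[j]) {
      inband[top[j]:bot[j], j] <- TRUE
    }
  }
  dark <- (sm < 0.18) & inband
  dk_lab <- EBImage::bwlabel(t(dark))
  dark_blobs <- sum(tabulate(as.integer(dk_lab)) > 25)
  bright_area <- mean(sm > 0.75)
  # bump count: upward excursions of the top of the bright outer band
  b <- apply(sm > 0.7, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) NA_real_ else min(w)
  })
  b[is.na(b)] <- stats::median(b, na.rm = TRUE)
  trend <- stats::filter(b, rep(1 / 31, 31), sides = 2)
  trend[is.na(trend)] <- b[is.na(trend)]
  resid <- b - as.numeric(trend)
  runs <- rle(resid < -2.5)
  bumps <- sum(runs$values & runs$lengths >= 3)
  c(thickness = thickness, dark_blobs = dark_blobs,
    bright_area = bright_area, bumps = bumps,
    variance = stats::var(as.numeric(image)))
}
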