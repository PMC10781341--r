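# Grad-CAM: gradient-weighted class activation mapping.

gradcam_layers <- function(model) {
  if (is.null(model$ffb)) paste0("stage", 1:4) else {
    c(paste0("fused", 1:4), paste0("stage", 1:4))
  }
}

#' Grad-CAM heatmap for one image
#'
#' Backpropagates the target-class logit to the selected feature map,
#' weights each channel by the spatial mean of its gradient, rectifies the
#' weighted activation sum, bilinearly upsamples to the input size, and
#' min-max normalizes to `[0, 1]` (an all-zero map stays all-zero).
#'
#' @param model A trained model.
#' @param image H x W matrix in `[0, 1]` (native resolution; it is resized
#'   to the model input internally).
#' @param norm_stats Normalization statistics used during training.
#' @param target_class Class index or name; defaults to the predicted class.
#' @param layer Feature map selector: `"fused1"`..`"fused4"` (finest fused
#'   map first; default) or `"stage1"`..`"stage4"` backbone outputs.
#' @return List with `heatmap` (input-sized matrix in `[0, 1]`),
#'   `target_class`, and `scores` (softmax vector).
#' @export
gradCAM <- function(model, image, norm_stats, target_class = NULL,
                    layer = NULL) {
  valid <- gradcam_layers(model)
  if (is.null(layer)) layer <- valid[1]
  if (!layer %in% valid) {
    stop("invalid layer '", layer, "'; valid layers: ",
         paste(valid, collapse = ", "))
  }
  size <- model$config$input_size
  x <- preprocessImage(image, size, norm_stats$mean, norm_stats$std)
  dim(x) <- c(size, size, 1L, 1L)
  ad_tape_begin()
  out <- model_forward_nodes(model, ad_input(x), training = FALSE)
  lg <- ad_val(out$logits)[, 1]
  p <- exp(lg - max(lg)); p <- p / sum(p)
  names(p) <- model$classes
  if (is.null(target_class)) target_class <- which.max(lg)
  if (is.character(target_class)) {
    target_class <- match(target_class, model$classes)
  }
  stopifnot(target_class >= 1, target_class <= length(lg))
  seed <- matrix(0, length(lg), 1)
  seed[target_class, 1] <- 1
  node <- if (grepl("^fused", layer)) {
    out$fused[[as.integer(sub("fused", "", layer))]]
  } else {
    out$stages[[as.integer(sub("stage", "", layer))]]
  }
  ad_backward(out$logits, seed)
  ad_tape_end()
  act <- ad_val(node)
  g <- node$grad
  if (is.null(g)) g <- act * 0
  d <- dim(act)
  w <- colMeans(matrix(g, nrow = d[1] * d[2]))  # per-channel gradient mean
  cam <- matrix(as.vector(matrix(act, nrow = d[1] * d[2]) %*% w), d[1], d[2])
  cam <- pmax(cam, 0)
  while (nrow(cam) < size) {
    a <- array(cam, dim = c(dim(cam), 1L, 1L))
    cam <- cpp_upsample2_fwd(a)[, , 1, 1]
  }
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  list(heatmap = cam, target_class = target_class, scores = p)
}

#' Write a Grad-CAM overlay PNG
#'
#' Renders the grayscale image with the heatmap blended in as a red-yellow
#' overlay.
#'
#' @param image H x W matrix in `[0, 1]`.
#' @param heatmap Matrix from [gradCAM()] (resized to match the image).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
writeGradCAMOverlay <- function(image, heatmap, path) {
  if (!all(dim(heatmap) == dim(image))) {
    heatmap <- resizeBilinear(heatmap, nrow(image), ncol(image))
  }
  a <- 0.5 * heatmap
  rgb <- array(0, dim = c(dim(image), 3))
  rgb[, , 1] <- (1 - a) * image + a * 1
  rgb[, , 2] <- (1 - a) * image + a * heatmap
  rgb[, , 3] <- (1 - a) * image
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
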