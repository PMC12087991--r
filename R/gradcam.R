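# Grad-CAM: gradients of a chosen scalar output (the leftover regression
# output, or one category's score) with respect to the last convolutional
# activation of one image's backbone path give per-channel weights; the
# weighted, rectified activation map is upsampled to the input size and
# max-normalized. A map whose rectified response is identically zero is
# returned as all zeros with the all_zero flag set (no features extracted
# for that output -- the known failure signature on oily dishes).

#' Core Grad-CAM combination
#'
#' Channel weights are the spatial means of the gradients; the map is the
#' rectified, weighted sum of activation channels, max-normalized to
#' `[0, 1]`. Exposed separately so the combination rule can be verified
#' against hand-computed values.
#'
#' @param activations H x W x C activation array of the target conv layer.
#' @param gradients Same-shape gradients of the target scalar.
#' @return List with `values` (H x W in `[0, 1]`) and `all_zero`.
#' @export
gradcam_core <- function(activations, gradients) {
  if (!identical(dim(activations), dim(gradients))) {
    stop("activations and gradients must have the same shape", call. = FALSE)
  }
  d <- dim(activations)
  w <- colMeans(matrix(gradients, d[1] * d[2], d[3]))
  m <- matrix(matrix(activations, d[1] * d[2], d[3]) %*% w, d[1], d[2])
  m <- pmax(m, 0)
  mx <- max(m)
  if (mx <= 0) {
    list(values = m * 0, all_zero = TRUE)
  } else {
    list(values = m / mx, all_zero = FALSE)
  }
}

#' Grad-CAM saliency map for a model and image pair
#'
#' @param model A built `intake_model` (convolutional backbone).
#' @param before,after Raw H x W x 3 image arrays of the pair.
#' @param task `"leftover"` (the regression output) or `"category"` (one
#'   class's score; unavailable for the single-task architectures).
#' @param target_class Food id whose score is explained for
#'   `task = "category"`; defaults to the predicted class.
#' @param which_image `"before"` or `"after"`: whose backbone path the map
#'   is computed on.
#' @param gt_id Ground-truth food id, needed by the `*_GT` architectures.
#' @return A `saliency_map`: list with `values` (input-size matrix in
#'   `[0, 1]`), `task`, `target_class`, `which_image`, `all_zero`.
#' @export
gradcam <- function(model, before, after, task = c("leftover", "category"),
                    target_class = NULL, which_image = c("before", "after"),
                    gt_id = NULL) {
  task <- match.arg(task)
  which_image <- match.arg(which_image)
  cfg <- model$config
  if (task == "category" && !(cfg$architecture %in% c("MT", "MT_IC", "MT_GT"))) {
    stop("contract error: ", cfg$architecture,
         " has no classification output", call. = FALSE)
  }
  xb <- .stack_images(list(before), cfg$backbone)
  xa <- .stack_images(list(after), cfg$backbone)
  gt <- if (!is.null(gt_id)) .one_hot(gt_id, cfg$n_categories)
  out <- .model_fwd(model, xb, xa, gt_onehot = gt, keep_cache = TRUE)
  if (task == "leftover") {
    dz <- 1
    dlogits <- NULL
  } else {
    if (is.null(target_class)) target_class <- predict_category(out$y_cat[, 1])
    dz <- 0
    dlogits <- .one_hot(target_class, cfg$n_categories)
  }
  bwd <- .model_bwd(model, out$cache, dz, dlogits)
  da <- if (which_image == "before") bwd$d_alast_before else bwd$d_alast_after
  acts <- if (which_image == "before") out$cache$bb$a_last else out$cache$ba$a_last
  d <- dim(acts)
  core <- gradcam_core(array(acts, d[1:3]), array(da, d[1:3]))
  sz <- cfg$backbone$input_size
  vals <- if (core$all_zero) {
    matrix(0, sz, sz)
  } else {
    up <- EBImage::resize(EBImage::Image(t(core$values)), w = sz, h = sz)
    v <- t(EBImage::imageData(up))
    v <- pmax(v, 0)
    v / max(v)
  }
  structure(list(values = vals, task = task,
                 target_class = if (task == "category") target_class,
                 which_image = which_image, all_zero = core$all_zero),
            class = "saliency_map")
}

.heat_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF", "#FFFF00",
                                 "#FF0000"))
  ramp(as.vector(v)) / 255
}

#' Render a saliency map over an image
#'
#' Alpha-blends a deterministic blue-to-red heat colormap over the image,
#' weighted by the map value: zero-valued locations keep the original
#' pixels, so an all-zero map returns the input unchanged.
#'
#' @param map A `saliency_map`.
#' @param image H x W x 3 array matching the map's size.
#' @param alpha Maximum blend weight.
#' @return H x W x 3 overlay array in `[0, 1]`.
#' @export
render_saliency <- function(map, image, alpha = 0.5) {
  d <- dim(image)
  if (length(d) != 3 || d[1] != nrow(map$values) || d[2] != ncol(map$values)) {
    stop("image and saliency map sizes do not match", call. = FALSE)
  }
  v <- map$values
  cols <- .heat_colors(v)
  out <- image
  w <- alpha * as.vector(v)
  for (ch in 1:3) {
    out[, , ch] <- image[, , ch] * (1 - w) + cols[, ch] * w
  }
  out
}

#' Save a saliency map
#'
#' Writes the rendered overlay as PNG and, optionally, the raw map as a
#' 32-bit float TIFF.
#'
#' @param map A `saliency_map`.
#' @param image The image to overlay.
#' @param png_path Overlay output path.
#' @param tiff_path Optional raw-map output path.
#' @return `png_path`, invisibly.
#' @export
save_saliency <- function(map, image, png_path, tiff_path = NULL) {
  overlay <- render_saliency(map, image)
  .write_png(overlay, png_path)
  if (!is.null(tiff_path)) {
    EBImage::writeImage(EBImage::Image(t(map$values)), tiff_path,
                        type = "tiff", bits.per.sample = 16L)
  }
  invisible(png_path)
}
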