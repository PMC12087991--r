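# Per-image feature extraction. The before and after images are encoded by
# one weight-tied (siamese) convolutional stack ending in global average
# pooling and a linear projection to the configured feature width, so that
# late fusion always concatenates two equal-length vectors.

.backbone_defaults <- list(
  "tiny-test" = list(stages = c(8, 16, 32), feat = 64, input = 64),
  vgg11 = list(stages = c(32, 64, 128, 256), feat = 2048, input = 224),
  vgg13 = list(stages = c(32, 64, 128, 256), feat = 2048, input = 224),
  vgg16 = list(stages = c(32, 64, 160, 320), feat = 2048, input = 224),
  vgg19 = list(stages = c(32, 64, 192, 384), feat = 2048, input = 224),
  resnet50 = list(stages = c(32, 64, 128, 256, 512), feat = 2048, input = 224),
  resnet101 = list(stages = c(48, 96, 192, 384, 768), feat = 2048, input = 224),
  resnet152 = list(stages = c(64, 128, 256, 512, 1024), feat = 2048, input = 224)
)

#' Backbone specification
#'
#' Names the feature-extraction stack and its interface dimensions. The
#' `tiny-test` backbone is a small stack trained from scratch, meant for
#' desk-scale experiments and tests. The named VGG/ResNet entries build
#' surrogate convolutional stacks of increasing capacity with the standard
#' 2048-wide projected feature interface; bundled pretrained weights are not
#' available, so `pretrained = TRUE` requires a `weights_file` saved by
#' [save_checkpoint()]-compatible tooling.
#'
#' @param name One of `"tiny-test"`, `"vgg11"`, `"vgg13"`, `"vgg16"`,
#'   `"vgg19"`, `"resnet50"`, `"resnet101"`, `"resnet152"`.
#' @param per_image_feature_dim Length of the per-image feature vector
#'   (stacks whose native pooled width differs are followed by a learned
#'   linear projection to it). Default: 64 for `tiny-test`, 2048 otherwise.
#' @param input_size Square input resolution the images are resized to.
#' @param pretrained Load weights from `weights_file` instead of random
#'   initialization.
#' @param weights_file Optional checkpoint path used when `pretrained`.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(name = "tiny-test", per_image_feature_dim = NULL,
                          input_size = NULL, pretrained = FALSE,
                          weights_file = NULL) {
  name <- match.arg(name, names(.backbone_defaults))
  def <- .backbone_defaults[[name]]
  feat <- as.integer(per_image_feature_dim %||% def$feat)
  input <- as.integer(input_size %||% def$input)
  stopifnot(feat > 0, input >= 8)
  if (pretrained && is.null(weights_file)) {
    stop("no pretrained weights are bundled for '", name,
         "'; pass weights_file = <checkpoint> or pretrained = FALSE",
         call. = FALSE)
  }
  structure(list(name = name, per_image_feature_dim = feat,
                 input_size = input, stages = def$stages,
                 pretrained = pretrained, weights_file = weights_file),
            class = "backbone_spec")
}

# parameter block for one backbone; names prefixed "bb_"
.init_backbone_params <- function(spec) {
  params <- list()
  c_in <- 3L
  for (i in seq_along(spec$stages)) {
    p <- .init_conv(3L, c_in, spec$stages[i])
    params[[paste0("bb_conv", i, "_w")]] <- p$w
    params[[paste0("bb_conv", i, "_b")]] <- p$b
    c_in <- spec$stages[i]
  }
  p <- .init_linear(c_in, spec$per_image_feature_dim)
  params$bb_proj_w <- p$w
  params$bb_proj_b <- p$b
  params
}

# x: (H, W, 3, N) preprocessed batch -> list(feat = F x N, cache)
.backbone_fwd <- function(params, spec, x, keep_cache = FALSE) {
  n_stage <- length(spec$stages)
  zs <- vector("list", n_stage)
  a <- x
  for (i in seq_len(n_stage)) {
    z <- .conv2d_forward(a, params[[paste0("bb_conv", i, "_w")]],
                         params[[paste0("bb_conv", i, "_b")]], 2L, 1L)
    zs[[i]] <- z
    a <- .relu(z)
  }
  a_last <- a
  g <- .gap_fwd(a_last)
  zf <- .linear_fwd(g, params$bb_proj_w, params$bb_proj_b)
  feat <- .relu(zf)
  cache <- if (keep_cache) list(x = x, zs = zs, a_last = a_last, g = g, zf = zf)
  list(feat = feat, cache = cache)
}

# dfeat: F x N upstream gradient -> list(grads (bb_*), d_alast)
.backbone_bwd <- function(params, spec, cache, dfeat) {
  grads <- list()
  dzf <- .relu_bwd(dfeat, cache$zf)
  lb <- .linear_bwd(dzf, cache$g, params$bb_proj_w)
  grads$bb_proj_w <- lb$dw
  grads$bb_proj_b <- lb$db
  da <- .gap_bwd(lb$dx, dim(cache$a_last))
  d_alast <- da
  n_stage <- length(spec$stages)
  for (i in rev(seq_len(n_stage))) {
    dz <- .relu_bwd(da, cache$zs[[i]])
    x_in <- if (i == 1) cache$x else .relu(cache$zs[[i - 1]])
    cb <- .conv2d_backward(x_in, params[[paste0("bb_conv", i, "_w")]], dz,
                           2L, 1L)
    grads[[paste0("bb_conv", i, "_w")]] <- cb$gw
    grads[[paste0("bb_conv", i, "_b")]] <- cb$gb
    da <- cb$gx
  }
  list(grads = grads, d_alast = d_alast)
}

#' Preprocess an image for a backbone
#'
#' Resizes to the backbone's input resolution (bilinear) and centers the
#' channels (`(x - 0.5) / 0.5`).
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param spec A [backbone_spec()].
#' @return `input_size` x `input_size` x 3 array.
#' @export
preprocess_image <- function(image, spec) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop("input error: expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (d[1] != spec$input_size || d[2] != spec$input_size) {
    image <- .from_ebi(EBImage::resize(.to_ebi(image), w = spec$input_size,
                                       h = spec$input_size))
  }
  (image - 0.5) / 0.5
}

#' Extract a per-image feature vector
#'
#' Runs the backbone's convolutional stack, global average pooling and the
#' linear projection, returning a fixed-length feature vector. Deterministic
#' for fixed weights (evaluation mode; the package uses no stochastic
#' layers).
#'
#' @param image H x W x 3 array in `[0, 1]` (resized internally).
#' @param backbone A built backbone (from [build_model()]'s `$backbone`,
#'   or a [backbone_spec()], in which case a randomly initialized stack is
#'   built on the fly).
#' @return Numeric vector of length `per_image_feature_dim`.
#' @export
extract_features <- function(image, backbone) {
  if (inherits(backbone, "backbone_spec")) {
    backbone <- list(spec = backbone, params = .init_backbone_params(backbone))
  }
  x <- preprocess_image(image, backbone$spec)
  x <- array(x, c(dim(x), 1L))
  as.vector(.backbone_fwd(backbone$params, backbone$spec, x)$feat)
}

#' Late fusion of before/after features
#'
#' Concatenates the two per-image feature vectors, before first, yielding
#' the fused vector the decision layers consume (length
#' `2 * per_image_feature_dim`; 4096 at the default 2048).
#'
#' @param before_features,after_features Equal-length numeric vectors.
#' @return Concatenated numeric vector.
#' @export
fuse <- function(before_features, after_features) {
  if (length(before_features) != length(after_features)) {
    stop("feature vectors must have equal length", call. = FALSE)
  }
  c(before_features, after_features)
}
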