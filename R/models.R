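# The five head wirings over the fused before/after features:
#   ST    fused -> FC1 -> FC2 -> regression output
#   ST_GT [fused (+) ground-truth one-hot] -> FC1+ -> FC2 -> regression
#   MT    fused -> shared FC1 -> {FC2 -> regression ; FC2' -> classification}
#   MT_IC as MT, but the classification branch's normalized score vector is
#         concatenated to the regression branch input before its own FC1+
#   MT_GT as MT_IC with the ground-truth one-hot fed back instead of the
#         predicted scores (upper-bound reference; same parameter shapes)
# The regression output is passed through a logistic nonlinearity when
# bounded_output is on, so the eaten fraction lands in [0, 1] by design.

.architectures <- c("ST", "ST_GT", "MT", "MT_IC", "MT_GT")

#' Model configuration
#'
#' @param backbone A [backbone_spec()].
#' @param architecture One of `"ST"`, `"ST_GT"`, `"MT"`, `"MT_IC"`,
#'   `"MT_GT"`.
#' @param n_categories Number of food categories the classification head
#'   emits (34 for the reference catalog; 50 reproduces the literal printed
#'   head width, the surplus treated as reserved capacity).
#' @param fc1_out,fc2_out Widths of the two decision layers (1024/512 at the
#'   published scale).
#' @param category_feedback For MT_IC: `"distribution"` feeds the softmax of
#'   the category logits (differentiable), `"hard-indicator"` the one-hot of
#'   the predicted class.
#' @param bounded_output Bound the regression output to `[0, 1]` with a
#'   logistic nonlinearity.
#' @return A `model_config` list; `fused_dim` is derived as
#'   `2 * per_image_feature_dim`.
#' @export
model_config <- function(backbone = backbone_spec(), architecture = "MT",
                         n_categories = 34, fc1_out = 1024, fc2_out = 512,
                         category_feedback = c("distribution", "hard-indicator"),
                         bounded_output = TRUE) {
  architecture <- match.arg(architecture, .architectures)
  category_feedback <- match.arg(category_feedback)
  stopifnot(inherits(backbone, "backbone_spec"), n_categories >= 1,
            fc1_out >= 1, fc2_out >= 1)
  structure(list(backbone = backbone, architecture = architecture,
                 n_categories = as.integer(n_categories),
                 fused_dim = 2L * backbone$per_image_feature_dim,
                 fc1_out = as.integer(fc1_out), fc2_out = as.integer(fc2_out),
                 category_feedback = category_feedback,
                 bounded_output = isTRUE(bounded_output)),
            class = "model_config")
}

.head_layer_dims <- function(config) {
  D <- config$fused_dim
  K <- config$n_categories
  h1 <- config$fc1_out
  h2 <- config$fc2_out
  dims <- list()
  arch <- config$architecture
  if (arch %in% c("ST", "MT", "MT_IC", "MT_GT")) dims$fc1 <- c(h1, D)
  if (arch %in% c("ST_GT", "MT_IC", "MT_GT")) dims$fc1p <- c(h1, D + K)
  dims$fc2 <- c(h2, h1)
  dims$out_r <- c(1L, h2)
  if (arch %in% c("MT", "MT_IC", "MT_GT")) {
    dims$fc2c <- c(h2, h1)
    dims$out_c <- c(K, h2)
  }
  dims
}

#' Build a model
#'
#' Initializes the siamese backbone (weight-tied across the before/after
#' paths) and the head layers for the requested architecture.
#'
#' @param config A [model_config()].
#' @param seed Optional seed for reproducible initialization.
#' @return An `intake_model` with elements `config`, `params` (flat named
#'   list of weight arrays).
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  params <- if (config$backbone$pretrained) {
    .load_backbone_weights(config$backbone)
  } else {
    .init_backbone_params(config$backbone)
  }
  for (nm in names(.head_layer_dims(config))) {
    d <- .head_layer_dims(config)[[nm]]
    p <- .init_linear(d[2], d[1])
    params[[paste0(nm, "_w")]] <- p$w
    params[[paste0(nm, "_b")]] <- p$b
  }
  structure(list(config = config, params = params), class = "intake_model")
}

.load_backbone_weights <- function(spec) {
  ck <- readRDS(spec$weights_file)
  ref <- .init_backbone_params(spec)
  for (nm in names(ref)) {
    if (is.null(ck$params[[nm]]) ||
        !identical(dim(ck$params[[nm]]) %||% length(ck$params[[nm]]),
                   dim(ref[[nm]]) %||% length(ref[[nm]]))) {
      stop("weights file does not match backbone '", spec$name, "' (", nm, ")",
           call. = FALSE)
    }
    ref[[nm]] <- ck$params[[nm]]
  }
  ref
}

#' @export
print.intake_model <- function(x, ...) {
  cat("<intake_model> ", x$config$architecture, " / ",
      x$config$backbone$name, ", ", format(n_params(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `intake_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# one-hot columns (K x N) for integer ids
.one_hot <- function(ids, K) {
  m <- matrix(0, K, length(ids))
  m[cbind(ids, seq_along(ids))] <- 1
  m
}

# Forward pass over preprocessed batches xb, xa: (H, W, 3, N).
# gt_onehot (K x N) is required by ST_GT and MT_GT; feedback_override
# replaces the MT_IC/MT_GT feedback vector (treated as a constant).
.model_fwd <- function(model, xb, xa, gt_onehot = NULL,
                       feedback_override = NULL, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  arch <- cfg$architecture
  bb <- .backbone_fwd(p, cfg$backbone, xb, keep_cache)
  ba <- .backbone_fwd(p, cfg$backbone, xa, keep_cache)
  fused <- rbind(bb$feat, ba$feat)
  N <- ncol(fused)
  if (arch == "ST_GT" && is.null(gt_onehot)) {
    stop("ST_GT requires the ground-truth category indicator", call. = FALSE)
  }
  if (arch == "MT_GT" && is.null(gt_onehot) && is.null(feedback_override)) {
    stop("MT_GT requires the ground-truth category indicator", call. = FALSE)
  }
  cc <- list(bb = bb$cache, ba = ba$cache, fused = fused)
  logits <- NULL
  if (arch == "ST") {
    z1 <- .linear_fwd(fused, p$fc1_w, p$fc1_b); h1 <- .relu(z1)
  } else if (arch == "ST_GT") {
    in0 <- rbind(fused, gt_onehot)
    z1 <- .linear_fwd(in0, p$fc1p_w, p$fc1p_b); h1 <- .relu(z1)
    cc$in0 <- in0
  } else if (arch == "MT") {
    z1 <- .linear_fwd(fused, p$fc1_w, p$fc1_b); h1 <- .relu(z1)
    z2c <- .linear_fwd(h1, p$fc2c_w, p$fc2c_b); h2c <- .relu(z2c)
    logits <- .linear_fwd(h2c, p$out_c_w, p$out_c_b)
    cc$z2c <- z2c; cc$h2c <- h2c
  } else {  # MT_IC / MT_GT
    z1c <- .linear_fwd(fused, p$fc1_w, p$fc1_b); h1c <- .relu(z1c)
    z2c <- .linear_fwd(h1c, p$fc2c_w, p$fc2c_b); h2c <- .relu(z2c)
    logits <- .linear_fwd(h2c, p$out_c_w, p$out_c_b)
    if (!is.null(feedback_override)) {
      fb <- feedback_override
      fb_diff <- FALSE
    } else if (arch == "MT_GT") {
      fb <- gt_onehot
      fb_diff <- FALSE
    } else if (cfg$category_feedback == "distribution") {
      fb <- .softmax_cols(logits)
      fb_diff <- TRUE
    } else {
      fb <- .one_hot(apply(logits, 2, which.max), cfg$n_categories)
      fb_diff <- FALSE
    }
    in_r <- rbind(fused, fb)
    z1 <- .linear_fwd(in_r, p$fc1p_w, p$fc1p_b); h1 <- .relu(z1)
    cc$z1c <- z1c; cc$h1c <- h1c; cc$z2c <- z2c; cc$h2c <- h2c
    cc$fb <- fb; cc$fb_diff <- fb_diff; cc$in_r <- in_r
  }
  z2 <- .linear_fwd(h1, p$fc2_w, p$fc2_b); h2 <- .relu(z2)
  z <- .linear_fwd(h2, p$out_r_w, p$out_r_b)
  y_lo <- if (cfg$bounded_output) .sigmoid(as.vector(z)) else as.vector(z)
  y_cat <- if (!is.null(logits)) .sigmoid(logits) else NULL
  cc$z1 <- z1; cc$h1 <- h1; cc$z2 <- z2; cc$h2 <- h2; cc$z <- z
  cc$logits <- logits
  list(y_lo = y_lo, y_cat = y_cat, logits = logits, z = as.vector(z),
       cache = if (keep_cache) cc)
}

# Backward pass. dz (length N) seeds the pre-bound regression output,
# dlogits (K x N or NULL) the pre-sigmoid category logits. Returns grads for
# every parameter plus the gradients at the last conv activations of the two
# image paths (for Grad-CAM).
.model_bwd <- function(model, cache, dz, dlogits = NULL) {
  cfg <- model$config
  p <- model$params
  arch <- cfg$architecture
  D <- cfg$fused_dim
  K <- cfg$n_categories
  grads <- list()
  add <- function(nm, g) grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g

  dz <- matrix(dz, nrow = 1)
  lb <- .linear_bwd(dz, cache$h2, p$out_r_w)
  add("out_r_w", lb$dw); add("out_r_b", lb$db)
  dz2 <- .relu_bwd(lb$dx, cache$z2)
  lb <- .linear_bwd(dz2, cache$h1, p$fc2_w)
  add("fc2_w", lb$dw); add("fc2_b", lb$db)
  dh1 <- lb$dx
  dlog_total <- dlogits

  if (arch == "ST") {
    dz1 <- .relu_bwd(dh1, cache$z1)
    lb <- .linear_bwd(dz1, cache$fused, p$fc1_w)
    add("fc1_w", lb$dw); add("fc1_b", lb$db)
    dfused <- lb$dx
  } else if (arch == "ST_GT") {
    dz1 <- .relu_bwd(dh1, cache$z1)
    lb <- .linear_bwd(dz1, cache$in0, p$fc1p_w)
    add("fc1p_w", lb$dw); add("fc1p_b", lb$db)
    dfused <- lb$dx[seq_len(D), , drop = FALSE]
  } else if (arch == "MT") {
    dz1 <- .relu_bwd(dh1, cache$z1)      # regression share of FC1 input grad
    dh1c <- NULL
    if (!is.null(dlog_total)) {
      lb <- .linear_bwd(dlog_total, cache$h2c, p$out_c_w)
      add("out_c_w", lb$dw); add("out_c_b", lb$db)
      dz2c <- .relu_bwd(lb$dx, cache$z2c)
      lb <- .linear_bwd(dz2c, cache$h1, p$fc2c_w)
      add("fc2c_w", lb$dw); add("fc2c_b", lb$db)
      dz1 <- dz1 + .relu_bwd(lb$dx, cache$z1)
    }
    lb <- .linear_bwd(dz1, cache$fused, p$fc1_w)
    add("fc1_w", lb$dw); add("fc1_b", lb$db)
    dfused <- lb$dx
  } else {  # MT_IC / MT_GT
    dz1 <- .relu_bwd(dh1, cache$z1)
    lb <- .linear_bwd(dz1, cache$in_r, p$fc1p_w)
    add("fc1p_w", lb$dw); add("fc1p_b", lb$db)
    dfused <- lb$dx[seq_len(D), , drop = FALSE]
    dfb <- lb$dx[D + seq_len(K), , drop = FALSE]
    if (isTRUE(cache$fb_diff)) {
      dfb_logits <- .softmax_bwd(dfb, cache$fb)
      dlog_total <- if (is.null(dlog_total)) dfb_logits
                    else dlog_total + dfb_logits
    }
    if (!is.null(dlog_total)) {
      lb <- .linear_bwd(dlog_total, cache$h2c, p$out_c_w)
      add("out_c_w", lb$dw); add("out_c_b", lb$db)
      dz2c <- .relu_bwd(lb$dx, cache$z2c)
      lb <- .linear_bwd(dz2c, cache$h1c, p$fc2c_w)
      add("fc2c_w", lb$dw); add("fc2c_b", lb$db)
      dz1c <- .relu_bwd(lb$dx, cache$z1c)
      lb <- .linear_bwd(dz1c, cache$fused, p$fc1_w)
      add("fc1_w", lb$dw); add("fc1_b", lb$db)
      dfused <- dfused + lb$dx
    }
  }

  Fdim <- D / 2
  db <- .backbone_bwd(p, cfg$backbone, cache$bb,
                      dfused[seq_len(Fdim), , drop = FALSE])
  da <- .backbone_bwd(p, cfg$backbone, cache$ba,
                      dfused[Fdim + seq_len(Fdim), , drop = FALSE])
  for (nm in names(db$grads)) add(nm, db$grads[[nm]] + da$grads[[nm]])
  list(grads = grads, d_alast_before = db$d_alast, d_alast_after = da$d_alast)
}

#' Decide the predicted food category
#'
#' Argmax over the per-category scores; ties break toward the lowest id.
#'
#' @param y_cat Numeric score vector, or a K x N matrix of per-column score
#'   vectors.
#' @return Integer food id(s) (1-based).
#' @export
predict_category <- function(y_cat) {
  if (is.matrix(y_cat)) {
    if (nrow(y_cat) == 0 || ncol(y_cat) == 0) {
      stop("empty score matrix", call. = FALSE)
    }
    return(apply(y_cat, 2, which.max))
  }
  if (length(y_cat) == 0) stop("empty score vector", call. = FALSE)
  which.max(y_cat)
}

#' Predict eaten fraction and category for image pairs
#'
#' @param model An `intake_model`.
#' @param pairs Named list of `list(before, after)` raw image arrays.
#' @param gt_ids Ground-truth food ids, required by the `*_GT`
#'   architectures.
#' @param batch_size Evaluation batch size.
#' @return List with `y_lo` (numeric, one per pair), `y_cat` (K x N score
#'   matrix or `NULL` for single-task models), `pred_id` (argmax ids or
#'   `NULL`).
#' @export
predict_pairs <- function(model, pairs, gt_ids = NULL, batch_size = 32) {
  UseMethod("predict_pairs")
}

#' @export
predict_pairs.intake_model <- function(model, pairs, gt_ids = NULL,
                                       batch_size = 32) {
  cfg <- model$config
  n <- length(pairs)
  y_lo <- numeric(n)
  y_cat <- NULL
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (ii in idx) {
    xb <- .stack_images(lapply(pairs[ii], `[[`, "before"), cfg$backbone)
    xa <- .stack_images(lapply(pairs[ii], `[[`, "after"), cfg$backbone)
    gt <- if (!is.null(gt_ids)) .one_hot(gt_ids[ii], cfg$n_categories)
    out <- .model_fwd(model, xb, xa, gt_onehot = gt)
    y_lo[ii] <- out$y_lo
    if (!is.null(out$y_cat)) {
      if (is.null(y_cat)) y_cat <- matrix(NA_real_, cfg$n_categories, n)
      y_cat[, ii] <- out$y_cat
    }
  }
  list(y_lo = y_lo, y_cat = y_cat,
       pred_id = if (!is.null(y_cat)) predict_category(y_cat))
}

.stack_images <- function(imgs, spec) {
  pre <- lapply(imgs, preprocess_image, spec = spec)
  out <- array(0, c(spec$input_size, spec$input_size, 3, length(pre)))
  for (i in seq_along(pre)) out[, , , i] <- pre[[i]]
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of the weights and the
#' configuration, with a JSON sidecar (`<path>.json`) describing the
#' configuration for inspection. Loading rebuilds the model and verifies
#' that every weight array matches the configuration's shapes.
#'
#' @param model An `intake_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); the model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$config
  ser <- list(backbone = list(name = cfg$backbone$name,
                              per_image_feature_dim = cfg$backbone$per_image_feature_dim,
                              input_size = cfg$backbone$input_size),
              architecture = cfg$architecture, n_categories = cfg$n_categories,
              fc1_out = cfg$fc1_out, fc2_out = cfg$fc2_out,
              category_feedback = cfg$category_feedback,
              bounded_output = cfg$bounded_output)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = ser, params = model$params), path)
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, pretty = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  s <- ck$config
  cfg <- model_config(backbone = backbone_spec(s$backbone$name,
                                               s$backbone$per_image_feature_dim,
                                               s$backbone$input_size),
                      architecture = s$architecture,
                      n_categories = s$n_categories, fc1_out = s$fc1_out,
                      fc2_out = s$fc2_out,
                      category_feedback = s$category_feedback,
                      bounded_output = s$bounded_output)
  model <- build_model(cfg, seed = 0)
  if (!setequal(names(model$params), names(ck$params))) {
    stop("checkpoint parameters do not match the configuration", call. = FALSE)
  }
  for (nm in names(model$params)) {
    a <- model$params[[nm]]; b <- ck$params[[nm]]
    if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
      stop("checkpoint shape mismatch for ", nm, call. = FALSE)
    }
  }
  model$params <- ck$params
  model
}
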