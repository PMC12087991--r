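# Training objective: an L1 penalty on the predicted eaten fraction against
# the scale-derived ground truth, a mean binary cross-entropy on the
# per-category scores, and their convex combination L = a*L_lo + (1-a)*L_cat
# with a = 0.9 by default, optimized with Adam and early stopping.

#' Leftover (eaten-fraction) regression loss
#'
#' `|y_lo - (weight_before - weight_after) / weight_before|`, elementwise.
#'
#' @param y_lo Predicted eaten fraction(s).
#' @param weight_before,weight_after Scale weights in grams.
#' @param clamp Passed to [compute_eaten_fraction()].
#' @return Numeric vector of absolute errors.
#' @export
leftover_loss <- function(y_lo, weight_before, weight_after, clamp = TRUE) {
  truth <- compute_eaten_fraction(weight_before, weight_after, clamp = clamp)
  abs(y_lo - truth)
}

#' Category classification loss
#'
#' Mean over categories of the binary cross-entropy between the score
#' vector and the one-hot indicator of the true label. Scores are clamped
#' to `[eps, 1 - eps]` so that hard 0/1 scores stay finite.
#'
#' @param y_cat Score vector in `[0, 1]` (length = number of categories), or
#'   a K x N matrix of score columns.
#' @param label True food id(s), in `1..K`.
#' @param eps Clamping epsilon.
#' @return Scalar loss (vector of per-column losses for matrix input).
#' @export
category_loss <- function(y_cat, label, eps = 1e-7) {
  if (!is.matrix(y_cat)) y_cat <- matrix(y_cat, ncol = 1)
  K <- nrow(y_cat)
  if (any(label < 1 | label > K)) {
    stop("label outside the catalog (1..", K, ")", call. = FALSE)
  }
  s <- pmin(pmax(y_cat, eps), 1 - eps)
  t <- .one_hot(as.integer(label), K)
  loss <- -colMeans(t * log(s) + (1 - t) * log(1 - s))
  if (length(loss) == 1) loss[[1]] else loss
}

#' Combined multi-task loss
#'
#' `alpha * l_lo + (1 - alpha) * l_cat`: linear in both losses, degenerating
#' to the leftover loss at `alpha = 1` and the category loss at `alpha = 0`.
#'
#' @param l_lo,l_cat Loss values.
#' @param alpha Task weight in `[0, 1]` (0.9 by default).
#' @return Numeric loss.
#' @export
combined_loss <- function(l_lo, l_cat, alpha = 0.9) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  alpha * l_lo + (1 - alpha) * l_cat
}

# ---- paired augmentation -------------------------------------------------

.augmentation_names <- c("hflip", "vflip", "rotate", "pad", "blur",
                         "sharpen", "contrast")

#' Draw one augmentation choice
#'
#' Selects exactly one of the seven transforms uniformly (probability 1/7
#' each) and draws its parameters: rotation angle up to +/-15 degrees,
#' reflection padding up to 10%, Gaussian blur sigma in 0.5--1.5, sharpness
#' amount in 0.5--1.5, contrast factor in 0.7--1.3. Uses R's RNG.
#'
#' @return List with `name` and `params`.
#' @export
select_augmentation <- function() {
  name <- .augmentation_names[sample.int(7L, 1L)]
  params <- switch(name,
    rotate = list(angle = runif(1, -15, 15)),
    pad = list(frac = runif(1, 0, 0.1)),
    blur = list(sigma = runif(1, 0.5, 1.5)),
    sharpen = list(amount = runif(1, 0.5, 1.5)),
    contrast = list(factor = runif(1, 0.7, 1.3)),
    list())
  list(name = name, params = params)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# nearest-neighbour rotation about the image centre, edge-extended
.rotate_img <- function(img, angle) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  sy <- round(cy + yy * cos(th) - xx * sin(th))
  sx <- round(cx + yy * sin(th) + xx * cos(th))
  sy <- pmin(pmax(sy, 1), H)
  sx <- pmin(pmax(sx, 1), W)
  out <- img
  idx <- cbind(as.vector(sy), as.vector(sx))
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    out[, , ch] <- matrix(plane[idx], H, W)
  }
  out
}

.reflect_pad <- function(img, p) {
  if (p < 1) return(img)
  d <- dim(img)
  ry <- c(rev(seq_len(min(p, d[1]))), seq_len(d[1]),
          d[1] - seq_len(min(p, d[1])) + 1)
  rx <- c(rev(seq_len(min(p, d[2]))), seq_len(d[2]),
          d[2] - seq_len(min(p, d[2])) + 1)
  img[ry, rx, , drop = FALSE]
}

.apply_augmentation <- function(img, tf) {
  d <- dim(img)
  switch(tf$name,
    hflip = img[, d[2]:1, , drop = FALSE],
    vflip = img[d[1]:1, , , drop = FALSE],
    rotate = .rotate_img(img, tf$params$angle),
    pad = {
      p <- round(tf$params$frac * d[1])
      if (p < 1) img else {
        padded <- .reflect_pad(img, p)
        .from_ebi(EBImage::resize(.to_ebi(padded), w = d[2], h = d[1]))
      }
    },
    blur = .from_ebi(EBImage::gblur(.to_ebi(img), sigma = tf$params$sigma)),
    sharpen = {
      blurred <- .from_ebi(EBImage::gblur(.to_ebi(img), sigma = 1))
      .clamp01(img + tf$params$amount * (img - blurred))
    },
    contrast = .clamp01((img - 0.5) * tf$params$factor + 0.5),
    stop("unknown transform ", tf$name, call. = FALSE))
}

#' Augment an image pair consistently
#'
#' One of the seven transforms is selected uniformly and applied with
#' identical parameters to both images, so the before/after comparison
#' geometry survives the augmentation.
#'
#' @param before,after Equal-size H x W x 3 arrays.
#' @param transform Optional pre-drawn [select_augmentation()] result.
#' @return List with `before`, `after`, and the applied `transform`.
#' @export
augment_pair <- function(before, after, transform = NULL) {
  if (!identical(dim(before), dim(after))) {
    stop("before/after images must have the same size", call. = FALSE)
  }
  tf <- transform %||% select_augmentation()
  list(before = .apply_augmentation(before, tf),
       after = .apply_augmentation(after, tf), transform = tf)
}

# ---- cross-validation folds ---------------------------------------------

#' Fold plan
#'
#' @param k Number of folds (default 10).
#' @param train_ratio,val_ratio,test_ratio Positive ratios summing to 1;
#'   with the 0.7/0.2/0.1 defaults and `k = 10`, fold i uses block i for
#'   testing, the next two blocks (cyclically) for validation and the
#'   remaining seven for training.
#' @param stratify_by_category Spread each category evenly over the blocks.
#' @return A `fold_plan` list.
#' @export
fold_plan <- function(k = 10, train_ratio = 0.7, val_ratio = 0.2,
                      test_ratio = 0.1, stratify_by_category = TRUE) {
  stopifnot(k >= 2, train_ratio > 0, val_ratio > 0, test_ratio > 0)
  if (abs(train_ratio + val_ratio + test_ratio - 1) > 1e-9) {
    stop("split ratios must sum to 1", call. = FALSE)
  }
  structure(list(k = as.integer(k), train_ratio = train_ratio,
                 val_ratio = val_ratio, test_ratio = test_ratio,
                 stratify_by_category = isTRUE(stratify_by_category)),
            class = "fold_plan")
}

#' Build cross-validation folds
#'
#' Partitions the pair ids into `k` blocks whose sizes differ by at most 1,
#' stratified by category; blocks carrying the `n %% k` surplus records are
#' spread evenly around the cyclic block order so every fold's train /
#' validation / test sizes stay within one record of the plan's ratios.
#' Fold i tests on block i, validates on the following `round(val_ratio*k)`
#' blocks (cyclically) and trains on the rest, so the k test sets partition
#' the whole dataset.
#'
#' @param table An [annotation_table()].
#' @param plan A [fold_plan()].
#' @param seed Shuffling seed.
#' @return List of `k` `fold_split` objects with `fold_index`, `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
make_folds <- function(table, plan = fold_plan(), seed = 1) {
  n <- nrow(table)
  k <- plan$k
  if (n < k) stop("k exceeds the number of records", call. = FALSE)
  set.seed(seed)
  base <- n %/% k
  r <- n %% k
  cap <- rep(base, k)
  if (r > 0) cap[floor((0:(r - 1)) * k / r) + 1] <- base + 1L
  blocks <- vector("list", k)
  cats <- if (plan$stratify_by_category) table$food_id else rep(1L, n)
  order_cat <- names(sort(table(cats), decreasing = TRUE))
  ptr <- 0L
  fill <- integer(k)
  for (cat in order_cat) {
    ids <- sample(table$pair_id[cats == cat])
    for (id in ids) {
      repeat {
        ptr <- ptr %% k + 1L
        if (fill[ptr] < cap[ptr]) break
      }
      blocks[[ptr]] <- c(blocks[[ptr]], id)
      fill[ptr] <- fill[ptr] + 1L
    }
  }
  n_test <- max(1L, round(plan$test_ratio * k))
  n_val <- max(1L, round(plan$val_ratio * k))
  if (n_test + n_val >= k) stop("no blocks left for training", call. = FALSE)
  cyc <- function(i) (i - 1L) %% k + 1L
  lapply(seq_len(k), function(i) {
    test_b <- cyc(i + seq_len(n_test) - 1L)
    val_b <- cyc(i + n_test + seq_len(n_val) - 1L)
    train_b <- setdiff(seq_len(k), c(test_b, val_b))
    structure(list(fold_index = i,
                   train_ids = unlist(blocks[train_b], use.names = FALSE),
                   val_ids = unlist(blocks[val_b], use.names = FALSE),
                   test_ids = unlist(blocks[test_b], use.names = FALSE)),
              class = "fold_split")
  })
}

# ---- training loop -------------------------------------------------------

#' Training configuration
#'
#' @param alpha Multi-task weight in `[0, 1]` (0.9).
#' @param learning_rate Adam learning rate (1e-4, the published fine-tuning
#'   rate; from-scratch training of the tiny backbone benefits from 1e-3).
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (20).
#' @param max_epochs Hard epoch cap.
#' @param batch_size Mini-batch size.
#' @param seed RNG seed covering shuffling, augmentation and initialization
#'   done inside [train()].
#' @param augment Apply [augment_pair()] to training pairs each epoch.
#' @param deterministic_mode Reserved switch kept for config compatibility;
#'   all operations in this implementation are deterministic given `seed`.
#' @param min_delta Minimum validation improvement that resets patience.
#' @return A `train_config` list.
#' @export
train_config <- function(alpha = 0.9, learning_rate = 1e-4, patience = 20,
                         max_epochs = 200, batch_size = 16, seed = 1,
                         augment = TRUE, deterministic_mode = TRUE,
                         min_delta = 1e-5) {
  stopifnot(alpha >= 0, alpha <= 1, learning_rate > 0, patience >= 1,
            max_epochs >= 1, batch_size >= 1, min_delta >= 0)
  structure(list(alpha = alpha, learning_rate = learning_rate,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = isTRUE(augment),
                 deterministic_mode = isTRUE(deterministic_mode),
                 min_delta = min_delta),
            class = "train_config")
}

#' Train a model on one fold
#'
#' Optimizes the combined loss (the leftover loss alone for the single-task
#' architectures) with Adam, monitoring the validation loss each epoch
#' (validation MAE for single-task models); stops after `patience`
#' consecutive epochs without improvement and restores the best-validation
#' weights.
#'
#' @param model An `intake_model`, or a dummy model (see
#'   [static_val_model()]) for harness tests.
#' @param dataset An [intake_dataset()].
#' @param split A `fold_split` from [make_folds()].
#' @param config A [train_config()].
#' @return A `training_result`: list with the trained `model` and `history`
#'   (data frame epoch/train_loss/val_loss/val_mae, with attributes
#'   `stopped_epoch` and `best_epoch`).
#' @export
train <- function(model, dataset, split, config = train_config()) {
  UseMethod("train")
}

.early_stop_state <- function() {
  list(best = Inf, best_epoch = 0L, bad = 0L)
}

.early_stop_update <- function(st, epoch, val, patience, min_delta) {
  if (val < st$best - min_delta) {
    st$best <- val
    st$best_epoch <- epoch
    st$bad <- 0L
    st$improved <- TRUE
  } else {
    st$bad <- st$bad + 1L
    st$improved <- FALSE
  }
  st$stop <- st$bad >= patience
  st
}

#' @export
train.intake_model <- function(model, dataset, split, config = train_config()) {
  cfg <- model$config
  arch <- cfg$architecture
  tab <- dataset$table
  if (!all(c(split$train_ids, split$val_ids) %in% tab$pair_id)) {
    stop("split ids not present in dataset", call. = FALSE)
  }
  if (length(split$train_ids) == 0 || length(split$val_ids) == 0) {
    stop("empty train or validation set", call. = FALSE)
  }
  set.seed(config$seed)
  rows <- function(ids) tab[match(ids, tab$pair_id), , drop = FALSE]
  tr <- rows(split$train_ids)
  va <- rows(split$val_ids)
  truth <- function(df) compute_eaten_fraction(df$weight_before_g,
                                               df$weight_after_g)
  tr_f <- truth(tr); va_f <- truth(va)
  pre <- function(ids) lapply(dataset$images[ids], function(p)
    list(before = preprocess_image(p$before, cfg$backbone),
         after = preprocess_image(p$after, cfg$backbone)))
  # keep raw copies for augmentation, preprocessed copies for the val set;
  # without augmentation the training batches never change, so preprocess
  # them once too
  tr_raw <- dataset$images[split$train_ids]
  tr_pre <- if (!config$augment) pre(split$train_ids)
  va_pre <- pre(split$val_ids)
  multitask <- arch %in% c("MT", "MT_IC", "MT_GT")
  alpha_eff <- if (multitask) config$alpha else 1
  state <- .adam_init(model$params)
  es <- .early_stop_state()
  best_params <- model$params
  hist <- vector("list", config$max_epochs)
  n_tr <- nrow(tr)

  batch_arrays <- function(pairs_pre) {
    sz <- cfg$backbone$input_size
    xb <- array(0, c(sz, sz, 3, length(pairs_pre)))
    xa <- xb
    for (i in seq_along(pairs_pre)) {
      xb[, , , i] <- pairs_pre[[i]]$before
      xa[, , , i] <- pairs_pre[[i]]$after
    }
    list(xb = xb, xa = xa)
  }

  validate <- function() {
    idx <- split(seq_along(va_pre), ceiling(seq_along(va_pre) / config$batch_size))
    l1 <- numeric(0); bce <- numeric(0)
    for (ii in idx) {
      ba <- batch_arrays(va_pre[ii])
      gt <- if (arch %in% c("ST_GT", "MT_GT")) .one_hot(va$food_id[ii], cfg$n_categories)
      out <- .model_fwd(model, ba$xb, ba$xa, gt_onehot = gt)
      l1 <- c(l1, abs(out$y_lo - va_f[ii]))
      if (multitask) bce <- c(bce, category_loss(out$y_cat, va$food_id[ii]))
    }
    val_mae <- mean(l1)
    val_loss <- if (multitask) combined_loss(mean(l1), mean(bce), config$alpha)
                else val_mae
    list(loss = val_loss, mae = val_mae)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      pairs <- if (config$augment) {
        lapply(tr_raw[bi], function(p) {
          ap <- augment_pair(p$before, p$after)
          list(before = preprocess_image(ap$before, cfg$backbone),
               after = preprocess_image(ap$after, cfg$backbone))
        })
      } else {
        tr_pre[bi]
      }
      ba <- batch_arrays(pairs)
      gt <- if (arch %in% c("ST_GT", "MT_GT")) .one_hot(tr$food_id[bi], cfg$n_categories)
      out <- .model_fwd(model, ba$xb, ba$xa, gt_onehot = gt, keep_cache = TRUE)
      nb <- length(bi)
      l1 <- abs(out$y_lo - tr_f[bi])
      loss <- alpha_eff * mean(l1)
      dy <- alpha_eff * sign(out$y_lo - tr_f[bi]) / nb
      dz <- if (cfg$bounded_output) dy * out$y_lo * (1 - out$y_lo) else dy
      dlogits <- NULL
      if (multitask) {
        t_mat <- .one_hot(tr$food_id[bi], cfg$n_categories)
        bce <- category_loss(out$y_cat, tr$food_id[bi])
        loss <- loss + (1 - config$alpha) * mean(bce)
        dlogits <- (1 - config$alpha) * (out$y_cat - t_mat) /
          (cfg$n_categories * nb)
      }
      bwd <- .model_bwd(model, out$cache, dz, dlogits)
      up <- .adam_step(model$params, bwd$grads, state, config$learning_rate)
      model$params <- up$params
      state <- up$state
      ep_loss <- ep_loss + loss * nb
    }
    v <- validate()
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n_tr,
                                val_loss = v$loss, val_mae = v$mae)
    es <- .early_stop_update(es, epoch, v$loss, config$patience,
                             config$min_delta)
    if (es$improved) best_params <- model$params
    if (es$stop || epoch == config$max_epochs) break
  }
  model$params <- best_params
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  attr(history, "stopped_epoch") <- max(history$epoch)
  attr(history, "best_epoch") <- es$best_epoch
  structure(list(model = model, history = history), class = "training_result")
}

#' Dummy model with a fixed validation loss
#'
#' A stand-in model whose validation loss is a constant (or a supplied
#' per-epoch sequence); [train()] on it exercises the early-stopping
#' bookkeeping without any optimization. Useful in tests of the training
#' harness.
#'
#' @param val_loss Constant validation loss, or a numeric vector indexed by
#'   epoch (recycled at the end).
#' @return A `static_val_model`.
#' @export
static_val_model <- function(val_loss = 0.5) {
  structure(list(val_loss = val_loss), class = "static_val_model")
}

#' @export
train.static_val_model <- function(model, dataset = NULL, split = NULL,
                                   config = train_config()) {
  es <- .early_stop_state()
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    v <- model$val_loss[min(epoch, length(model$val_loss))]
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = NA_real_,
                                val_loss = v, val_mae = v)
    es <- .early_stop_update(es, epoch, v, config$patience, config$min_delta)
    if (es$stop) break
  }
  history <- do.call(rbind, hist)
  attr(history, "stopped_epoch") <- max(history$epoch)
  attr(history, "best_epoch") <- es$best_epoch
  structure(list(model = model, history = history), class = "training_result")
}

#' Write a training history to CSV
#'
#' @param result A `training_result` from [train()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(result, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}

#' Bundle an annotation table with its images
#'
#' @param table An [annotation_table()].
#' @param images Named list (by `pair_id`) of `list(before, after)` arrays;
#'   when `NULL`, images are loaded from `root` using the table's image
#'   references (or taken from the table's `"images"` attribute as produced
#'   by [generate_dataset()] with `write_images = FALSE`).
#' @param root Directory image references are relative to.
#' @return An `intake_dataset` list with `table` and `images`.
#' @export
intake_dataset <- function(table, images = NULL, root = NULL) {
  if (is.null(images)) images <- attr(table, "images")
  if (is.null(images)) {
    if (is.null(root)) stop("need images or a dataset root", call. = FALSE)
    images <- lapply(seq_len(nrow(table)), function(i) {
      list(before = read_image(file.path(root, table$before_image[i])),
           after = read_image(file.path(root, table$after_image[i])))
    })
    names(images) <- table$pair_id
  }
  if (!all(table$pair_id %in% names(images))) {
    stop("missing images for some pair_ids", call. = FALSE)
  }
  structure(list(table = table, images = images[table$pair_id]),
            class = "intake_dataset")
}
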