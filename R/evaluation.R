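# Metrics and the cross-validated evaluation harness. MAE is computed on
# the eaten-fraction scale; classification accuracy on exact id matches;
# the human baseline scores the observer's 1-7 level (mapped to level/7)
# against the scale-derived fraction.

#' Mean absolute error
#'
#' @param predictions,truths Equal-length numeric vectors of eaten
#'   fractions.
#' @return Scalar MAE.
#' @export
mae <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop("predictions and truths must be equal-length and non-empty",
         call. = FALSE)
  }
  mean(abs(predictions - truths))
}

#' Class-wise mean absolute error
#'
#' MAE restricted to each category's records; categories absent from the
#' evaluation set are omitted.
#'
#' @param predictions,truths Aligned numeric vectors.
#' @param food_ids Aligned integer category ids.
#' @param catalog Catalog used to validate the ids.
#' @return Named numeric vector keyed by food id (sorted).
#' @export
classwise_mae <- function(predictions, truths, food_ids,
                          catalog = food_catalog()) {
  if (length(predictions) != length(truths) ||
      length(predictions) != length(food_ids)) {
    stop("inputs must be aligned", call. = FALSE)
  }
  if (any(!food_ids %in% catalog$food_id)) {
    stop("unknown food_id in evaluation set", call. = FALSE)
  }
  err <- abs(predictions - truths)
  out <- vapply(split(err, food_ids), mean, numeric(1))
  out[order(as.integer(names(out)))]
}

#' Classification accuracy
#'
#' @param predicted_ids,true_ids Aligned non-empty integer vectors.
#' @return Fraction of exact matches in `[0, 1]`.
#' @export
classification_accuracy <- function(predicted_ids, true_ids) {
  if (length(predicted_ids) == 0 || length(predicted_ids) != length(true_ids)) {
    stop("id vectors must be equal-length and non-empty", call. = FALSE)
  }
  mean(predicted_ids == true_ids)
}

#' Human-observer baseline MAE
#'
#' Scores the Comstock-style visual rating against the scale ground truth:
#' the mean over records of `|level / 7 - eaten_fraction|`.
#'
#' @param table A non-empty [annotation_table()].
#' @param clamp Passed to [compute_eaten_fraction()].
#' @return Scalar MAE of the human observation.
#' @export
human_baseline_mae <- function(table, clamp = TRUE) {
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  truth <- tryCatch(
    compute_eaten_fraction(table$weight_before_g, table$weight_after_g,
                           clamp = clamp),
    error = function(e) {
      stop("invalid weights in table (first pair_id ", table$pair_id[1],
           "): ", conditionMessage(e), call. = FALSE)
    })
  mean(abs(observer_level_to_fraction(table$observer_level) - truth))
}

#' Per-level weight statistics and level-fraction correlation
#'
#' For each observer level present, the mean and SD of the normalized
#' leftover weight (`weight_after / weight_before`) and of the eaten
#' fraction, plus the Pearson correlation between observer level and eaten
#' fraction.
#'
#' @param table An [annotation_table()] with at least two distinct levels.
#' @return A `level_weight_stats` list: `per_level` data frame (level, n,
#'   mean/sd of leftover weight and eaten fraction) and `pearson_r`.
#' @export
level_weight_stats <- function(table) {
  if (nrow(table) < 2 || length(unique(table$observer_level)) < 2) {
    stop("correlation undefined: need at least two distinct levels",
         call. = FALSE)
  }
  eaten <- compute_eaten_fraction(table$weight_before_g, table$weight_after_g)
  leftover <- 1 - eaten
  lv <- factor(table$observer_level, levels = sort(unique(table$observer_level)))
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  per <- data.frame(level = as.integer(levels(lv)),
                    n = as.integer(table(lv)),
                    mean_leftover = vapply(split(leftover, lv), mean, 1),
                    sd_leftover = vapply(split(leftover, lv), sd0, 1),
                    mean_eaten = vapply(split(eaten, lv), mean, 1),
                    sd_eaten = vapply(split(eaten, lv), sd0, 1))
  rownames(per) <- NULL
  if (sd(eaten) == 0) {
    stop("correlation undefined: eaten fraction is constant", call. = FALSE)
  }
  structure(list(per_level = per,
                 pearson_r = cor(table$observer_level, eaten)),
            class = "level_weight_stats")
}

#' @export
print.level_weight_stats <- function(x, ...) {
  cat("<level_weight_stats> Pearson r(level, eaten fraction) =",
      format(x$pearson_r, digits = 4), "\n")
  print(x$per_level, digits = 3)
  invisible(x)
}

# ---- reference (dummy) models for the harness ---------------------------

#' Reference models for harness checks
#'
#' `oracle_model()` returns the true fraction and category of every pair;
#' `global_mean_model(value)` predicts a constant fraction (typically the
#' training-set mean); `constant_model(value)` is its alias without the
#' training-mean connotation. None of them trains.
#'
#' @param value Constant predicted eaten fraction.
#' @return A model object usable with [predict_pairs()] and
#'   [cross_validated_evaluate()].
#' @export
oracle_model <- function() {
  structure(list(), class = c("oracle_model", "reference_model"))
}

#' @rdname oracle_model
#' @export
global_mean_model <- function(value) {
  structure(list(value = value),
            class = c("constant_model", "reference_model"))
}

#' @rdname oracle_model
#' @export
constant_model <- function(value) global_mean_model(value)

#' @export
predict_pairs.reference_model <- function(model, pairs, gt_ids = NULL,
                                          batch_size = 32) {
  stop("reference models predict from the annotation table; use ",
       "cross_validated_evaluate()", call. = FALSE)
}

.reference_predict <- function(model, tab, ids) {
  df <- tab[match(ids, tab$pair_id), , drop = FALSE]
  truth <- compute_eaten_fraction(df$weight_before_g, df$weight_after_g)
  if (inherits(model, "oracle_model")) {
    list(y_lo = truth, pred_id = df$food_id)
  } else {
    list(y_lo = rep(model$value, length(ids)), pred_id = NULL)
  }
}

# ---- cross-validated evaluation -----------------------------------------

#' Cross-validated evaluation
#'
#' Trains one model per fold (models without trainable parameters are
#' evaluated directly), scores each fold's test set, and aggregates: mean
#' and SD over folds of the MAE and the classification accuracy, plus the
#' class-wise MAE pooled over the concatenated test folds (per-fold class
#' counts can be zero for rare categories, so pooling is used).
#'
#' @param model_factory Function `(fold_split) -> model`; may close over
#'   the dataset (e.g. to build a [global_mean_model()] from the fold's
#'   training records).
#' @param dataset An [intake_dataset()] (reference models need only its
#'   `table`).
#' @param folds Folds from [make_folds()] on the same table.
#' @param config A [train_config()].
#' @return A `metrics_report` list: `mae`, `mae_sd_over_folds`, `accuracy`,
#'   `accuracy_sd_over_folds`, `per_food_mae`, `n_evaluated`, `per_fold`.
#' @export
cross_validated_evaluate <- function(model_factory, dataset, folds,
                                     config = train_config()) {
  tab <- if (inherits(dataset, "intake_dataset")) dataset$table else dataset
  all_ids <- unlist(lapply(folds, `[[`, "test_ids"), use.names = FALSE)
  if (!all(all_ids %in% tab$pair_id)) {
    stop("folds do not match the dataset", call. = FALSE)
  }
  catalog <- attr(tab, "catalog") %||% food_catalog()
  pool_pred <- numeric(0); pool_truth <- numeric(0); pool_food <- integer(0)
  per_fold <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    model <- model_factory(fold)
    if (inherits(model, "intake_model")) {
      fit <- train(model, dataset, fold, config)
      model <- fit$model
      df <- tab[match(fold$test_ids, tab$pair_id), , drop = FALSE]
      pred <- predict_pairs(model, dataset$images[fold$test_ids],
                            gt_ids = df$food_id)
      y_lo <- pred$y_lo
      pred_id <- pred$pred_id
    } else {
      rp <- .reference_predict(model, tab, fold$test_ids)
      df <- tab[match(fold$test_ids, tab$pair_id), , drop = FALSE]
      y_lo <- rp$y_lo
      pred_id <- rp$pred_id
    }
    truth <- compute_eaten_fraction(df$weight_before_g, df$weight_after_g)
    acc <- if (!is.null(pred_id)) classification_accuracy(pred_id, df$food_id)
           else NA_real_
    per_fold[[i]] <- data.frame(fold = fold$fold_index,
                                n_test = length(fold$test_ids),
                                mae = mae(y_lo, truth), accuracy = acc)
    pool_pred <- c(pool_pred, y_lo)
    pool_truth <- c(pool_truth, truth)
    pool_food <- c(pool_food, df$food_id)
  }
  pf <- do.call(rbind, per_fold)
  report <- list(mae = mean(pf$mae),
                 mae_sd_over_folds = if (nrow(pf) > 1) sd(pf$mae) else 0,
                 accuracy = if (all(is.na(pf$accuracy))) NA_real_
                            else mean(pf$accuracy),
                 accuracy_sd_over_folds = if (all(is.na(pf$accuracy))) NA_real_
                   else if (nrow(pf) > 1) sd(pf$accuracy) else 0,
                 per_food_mae = classwise_mae(pool_pred, pool_truth, pool_food,
                                              catalog = catalog),
                 n_evaluated = length(pool_pred),
                 per_fold = pf)
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n_evaluated, "\n")
  cat(sprintf("  MAE:      %.4f (%.4f over folds)\n", x$mae,
              x$mae_sd_over_folds))
  if (!is.na(x$accuracy)) {
    cat(sprintf("  accuracy: %.4f (%.4f over folds)\n", x$accuracy,
                x$accuracy_sd_over_folds))
  }
  invisible(x)
}

#' Serialize a metrics report
#'
#' `metrics_report_json()` writes/returns the documented JSON schema;
#' `metrics_report_csv()` writes one flat row per report (model x backbone
#' sweep style) and `classwise_mae_csv()` the per-category MAE table.
#'
#' @param report A `metrics_report`.
#' @param path Output path (`NULL` returns the JSON string).
#' @param label Row label used in the flat CSV.
#' @return The JSON string or `path`, invisibly.
#' @export
metrics_report_json <- function(report, path = NULL) {
  obj <- list(mae = report$mae, mae_sd_over_folds = report$mae_sd_over_folds,
              accuracy = report$accuracy,
              accuracy_sd_over_folds = report$accuracy_sd_over_folds,
              per_food_mae = as.list(report$per_food_mae),
              n_evaluated = report$n_evaluated)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname metrics_report_json
#' @export
metrics_report_csv <- function(report, path, label = "model") {
  df <- data.frame(model = label, mae = report$mae,
                   mae_sd = report$mae_sd_over_folds,
                   accuracy = report$accuracy,
                   accuracy_sd = report$accuracy_sd_over_folds,
                   n = report$n_evaluated)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (file.exists(path)) {
    write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE,
                append = TRUE)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname metrics_report_json
#' @export
classwise_mae_csv <- function(report, path) {
  df <- data.frame(food_id = as.integer(names(report$per_food_mae)),
                   mae = as.numeric(report$per_food_mae))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Round-trip a metrics report from its JSON form
#' @param json JSON string or file path produced by [metrics_report_json()].
#' @return A `metrics_report` (without the per-fold detail).
#' @export
metrics_report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  report <- list(mae = obj$mae, mae_sd_over_folds = obj$mae_sd_over_folds,
                 accuracy = obj$accuracy %||% NA_real_,
                 accuracy_sd_over_folds = obj$accuracy_sd_over_folds %||% NA_real_,
                 per_food_mae = setNames(as.numeric(obj$per_food_mae),
                                         names(obj$per_food_mae)),
                 n_evaluated = obj$n_evaluated, per_fold = NULL)
  class(report) <- "metrics_report"
  report
}
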