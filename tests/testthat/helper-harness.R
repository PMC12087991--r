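# Desk-scale parameter-recovery harness: 8 categories x 50 pairs rendered at
# 64 px, fixed seed, tiny-test backbone trained from scratch (Adam 1e-3, the
# stock from-scratch rate; the package default 1e-4 is a fine-tuning rate).
# Trained at most once per test run and shared between the recovery and
# saliency tests.
.harness_env <- new.env(parent = emptyenv())

recovery_data <- function() {
  if (is.null(.harness_env$ds)) {
    tab <- generate_dataset(generation_spec(8, 50, seed = 11),
                            scene_config(image_size = 64))
    .harness_env$ds <- intake_dataset(tab)
    .harness_env$folds <- make_folds(tab, fold_plan(), seed = 11)
  }
  list(ds = .harness_env$ds, fold = .harness_env$folds[[1]])
}

recovery_fit <- function(arch = "MT") {
  key <- paste0("fit_", arch)
  if (is.null(.harness_env[[key]])) {
    hd <- recovery_data()
    cfg <- model_config(backbone_spec("tiny-test"), arch, n_categories = 8,
                        fc1_out = 64, fc2_out = 32)
    tc <- train_config(learning_rate = 1e-3, max_epochs = 150,
                       augment = FALSE, seed = 11)
    .harness_env[[key]] <- train(build_model(cfg, seed = 11), hd$ds, hd$fold,
                                 tc)
  }
  c(recovery_data(), list(fit = .harness_env[[key]]))
}

recovery_test_metrics <- function(arch) {
  h <- recovery_fit(arch)
  df <- h$ds$table[match(h$fold$test_ids, h$ds$table$pair_id), ]
  pred <- predict_pairs(h$fit$model, h$ds$images[h$fold$test_ids])
  truth <- compute_eaten_fraction(df$weight_before_g, df$weight_after_g)
  tr_df <- h$ds$table[match(h$fold$train_ids, h$ds$table$pair_id), ]
  gm <- mean(compute_eaten_fraction(tr_df$weight_before_g,
                                    tr_df$weight_after_g))
  list(mae = mae(pred$y_lo, truth),
       baseline_mae = mae(rep(gm, length(truth)), truth),
       accuracy = classification_accuracy(pred$pred_id, df$food_id))
}
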