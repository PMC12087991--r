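# Shared fixtures, all generated in code.

# 524-record annotation table mirroring the reference survey's per-category
# and per-level counts; eaten fractions sit exactly on the level anchors
# unless jitter_sd > 0 (then they get deterministic-seeded Gaussian jitter,
# clamped to [0, 1]).
ref_fixture_table <- function(jitter_sd = 0, seed = 101) {
  counts <- reference_pair_counts()
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    lv <- rep(1:7, times = as.integer(counts[i, paste0("l", 1:7)]))
    if (!length(lv)) return(NULL)
    f <- lv / 7
    if (jitter_sd > 0) f <- pmin(pmax(f + rnorm(length(f), 0, jitter_sd), 0), 1)
    wb <- runif(length(lv), 80, 300)
    data.frame(pair_id = sprintf("p%02d_%03d", i, seq_along(lv)),
               food_id = i, weight_before_g = wb,
               weight_after_g = wb * (1 - f), observer_level = lv,
               stringsAsFactors = FALSE)
  }))
  annotation_table(recs)
}

# uniformly random annotation table over the full catalog
random_table <- function(n, seed = 7) {
  set.seed(seed)
  wb <- runif(n, 50, 400)
  f <- runif(n)
  annotation_table(data.frame(
    pair_id = sprintf("r%04d", seq_len(n)),
    food_id = sample.int(34, n, replace = TRUE),
    weight_before_g = wb, weight_after_g = wb * (1 - f),
    observer_level = sample.int(7, n, replace = TRUE)))
}

# small model configuration for fast tests
tiny_model_cfg <- function(arch = "MT", K = 4, feat = 12, input = 16,
                           fc1 = 10, fc2 = 6) {
  model_config(backbone_spec("tiny-test", per_image_feature_dim = feat,
                             input_size = input),
               architecture = arch, n_categories = K,
               fc1_out = fc1, fc2_out = fc2)
}

# in-memory synthetic dataset at reduced resolution
tiny_dataset <- function(n_categories = 4, pairs = 10, seed = 5,
                         image_size = 32) {
  tab <- generate_dataset(generation_spec(n_categories, pairs, seed = seed),
                          scene_config(image_size = image_size))
  intake_dataset(tab)
}

# independent colour-mask pixel counter for a category's food region
count_food_pixels <- function(img, style, tol = 0.35) {
  col <- grDevices::col2rgb(grDevices::hsv(style$hue / 360, 0.85, 0.72))[, 1] / 255
  d <- sqrt((img[, , 1] - col[1])^2 + (img[, , 2] - col[2])^2 +
              (img[, , 3] - col[3])^2)
  sum(d < tol)
}
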