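test_that("feature extraction obeys the shape and determinism contracts", {
  bb <- backbone_spec("tiny-test", per_image_feature_dim = 12, input_size = 16)
  built <- list(spec = bb,
                params = local({ set.seed(4); mealintake:::.init_backbone_params(bb) }))
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  f1 <- extract_features(img, built)
  expect_length(f1, 12L)
  expect_identical(f1, extract_features(img, built))

  black <- array(0, c(16, 16, 3))
  white <- array(1, c(16, 16, 3))
  expect_false(isTRUE(all.equal(extract_features(black, built),
                                extract_features(white, built))))
  expect_error(extract_features(array(0, c(16, 16, 2)), built), "input error")
})

test_that("late fusion concatenates before-first at twice the width", {
  u <- runif(2048)
  v <- runif(2048)
  expect_length(fuse(u, v), 4096L)
  expect_identical(fuse(u, v), c(u, v))
  expect_false(identical(fuse(u, v), fuse(v, u)))
  expect_identical(fuse(numeric(3), numeric(3)), numeric(6))
  expect_error(fuse(u, v[-1]), "equal length")
})

test_that("head widths trace the configuration for any dims", {
  # published-scale check: ST_GT first layer consumes 4096 + 34 = 4130
  cfg <- model_config(backbone_spec("resnet50"), "ST_GT")
  m <- build_model(cfg, seed = 1)
  expect_equal(dim(m$params$fc1p_w), c(1024L, 4130L))
  expect_equal(cfg$fused_dim, 4096L)

  for (arch in c("ST", "ST_GT", "MT", "MT_IC", "MT_GT")) {
    for (feat in c(8L, 20L)) {
      for (K in c(3L, 9L)) {
        cfg <- model_config(backbone_spec("tiny-test", feat, 16), arch,
                            n_categories = K, fc1_out = 11, fc2_out = 5)
        m <- build_model(cfg, seed = 2)
        D <- 2L * feat
        if (arch %in% c("ST", "MT", "MT_IC", "MT_GT")) {
          expect_equal(dim(m$params$fc1_w), c(11L, D))
        }
        if (arch %in% c("ST_GT", "MT_IC", "MT_GT")) {
          expect_equal(dim(m$params$fc1p_w), c(11L, D + K))
        }
        expect_equal(dim(m$params$fc2_w), c(5L, 11L))
        expect_equal(dim(m$params$out_r_w), c(1L, 5L))
        if (arch %in% c("MT", "MT_IC", "MT_GT")) {
          expect_equal(dim(m$params$out_c_w), c(K, 5L))
        } else {
          expect_null(m$params$out_c_w)
        }
      }
    }
  }
})

test_that("bounded output pins zeroed final layers at 0.5 and stays in [0,1]", {
  cfg <- tiny_model_cfg("MT")
  m <- build_model(cfg, seed = 3)
  m$params$out_r_w[] <- 0
  m$params$out_r_b[] <- 0
  set.seed(5)
  xb <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  xa <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  out <- mealintake:::.model_fwd(m, xb, xa)
  expect_equal(out$y_lo, c(0.5, 0.5))

  # arbitrary (large) weights still give bounded predictions
  m2 <- build_model(cfg, seed = 4)
  for (nm in names(m2$params)) m2$params[[nm]] <- m2$params[[nm]] * 50
  out2 <- mealintake:::.model_fwd(m2, xb, xa)
  expect_true(all(out2$y_lo >= 0 & out2$y_lo <= 1))
})

test_that("the multi-task head adds parameters over the single-task head", {
  st <- build_model(tiny_model_cfg("ST"), seed = 1)
  mt <- build_model(tiny_model_cfg("MT"), seed = 1)
  expect_gt(n_params(mt), n_params(st))
})

test_that("category decisions take the first maximal score", {
  expect_equal(predict_category(c(0.1, 0.9, 0.3)), 2L)
  expect_equal(predict_category(c(0.5, 0.5)), 1L)
  expect_error(predict_category(numeric(0)), "empty")
  set.seed(6)
  for (i in 1:20) {
    v <- runif(34)
    linear_scan <- which(v == max(v))[1]
    expect_equal(predict_category(v), linear_scan)
  }
})

test_that("MT_GT equals MT_IC when feedback is the ground-truth indicator", {
  cfg_ic <- tiny_model_cfg("MT_IC")
  cfg_gt <- tiny_model_cfg("MT_GT")
  ic <- build_model(cfg_ic, seed = 8)
  gt <- build_model(cfg_gt, seed = 123)
  gt$params <- ic$params  # same shapes by design
  set.seed(9)
  xb <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  xa <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  onehot <- mealintake:::.one_hot(c(1L, 4L, 2L), 4L)
  out_gt <- mealintake:::.model_fwd(gt, xb, xa, gt_onehot = onehot)
  out_ic <- mealintake:::.model_fwd(ic, xb, xa, feedback_override = onehot)
  expect_equal(out_gt$y_lo, out_ic$y_lo, tolerance = 1e-12)
  expect_equal(out_gt$y_cat, out_ic$y_cat, tolerance = 1e-12)
})

test_that("architectures enforce their input contracts", {
  gtm <- build_model(tiny_model_cfg("ST_GT"), seed = 1)
  xb <- array(0.5, c(16, 16, 3, 1))
  expect_error(mealintake:::.model_fwd(gtm, xb, xb), "ground-truth")
  st <- build_model(tiny_model_cfg("ST"), seed = 1)
  expect_null(mealintake:::.model_fwd(st, xb, xb)$y_cat)
})

test_that("checkpoints round-trip weights and verify shapes", {
  m <- build_model(tiny_model_cfg("MT_IC"), seed = 10)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_equal(back$params, m$params)
  expect_equal(back$config$architecture, "MT_IC")

  # corrupt a shape -> refuse to load
  ck <- readRDS(path)
  ck$params$fc2_w <- ck$params$fc2_w[, -1]
  saveRDS(ck, path)
  expect_error(load_checkpoint(path), "shape mismatch")
})

test_that("pretrained backbones demand a weights file", {
  expect_error(backbone_spec("resnet101", pretrained = TRUE),
               "weights_file")
})
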