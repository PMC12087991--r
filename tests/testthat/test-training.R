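test_that("leftover loss vanishes exactly at the true fraction", {
  expect_equal(leftover_loss(0.7, 100, 30), 0.0)
  expect_equal(leftover_loss(0.5, 100, 30), 0.2)
  expect_equal(leftover_loss(0.0, 100, 100), 0.0)
  set.seed(11)
  for (i in 1:20) {
    wb <- runif(1, 1, 300); wa <- runif(1, 0, wb); y <- runif(1)
    f <- compute_eaten_fraction(wb, wa)
    expect_equal(leftover_loss(f, wb, wa), 0)
    expect_equal(leftover_loss(y, wb, wa), abs(y - f))
    expect_true(leftover_loss(y, wb, wa) <= 1)
  }
})

test_that("category loss matches its closed forms and a per-term oracle", {
  # indicator scores (after epsilon clamping) give ~0
  expect_lt(category_loss(c(0, 1, 0), 2L), 1e-5)
  # uniform 0.5 scores over C = 2 give ln 2
  expect_equal(category_loss(c(0.5, 0.5), 1L), log(2), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    K <- sample(2:10, 1)
    s <- runif(K, 0.01, 0.99)
    lab <- sample.int(K, 1)
    t <- as.numeric(seq_len(K) == lab)
    oracle <- -mean(t * log(s) + (1 - t) * log(1 - s))
    expect_equal(category_loss(s, lab), oracle, tolerance = 1e-9)
  }
  expect_error(category_loss(c(0.5, 0.5), 3L), "catalog")
})

test_that("the combined loss is the stated convex combination", {
  expect_identical(combined_loss(1.0, 0.0, 0.9), 0.9)
  expect_equal(combined_loss(0.1, 0.5, 0.9), 0.14, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:10) {
    l1 <- runif(1); l2 <- runif(1); a <- runif(1)
    expect_equal(combined_loss(l1, l2, 1.0), l1, tolerance = 1e-12)
    expect_equal(combined_loss(l1, l2, 0.0), l2, tolerance = 1e-12)
    # linearity in each argument
    expect_equal(combined_loss(2 * l1, l2, a) - combined_loss(l1, l2, a),
                 a * l1, tolerance = 1e-12)
    expect_equal(combined_loss(l1, 2 * l2, a) - combined_loss(l1, l2, a),
                 (1 - a) * l2, tolerance = 1e-12)
  }
  expect_error(combined_loss(1, 1, 1.5), "alpha")
})

test_that("paired augmentation picks one transform and applies it to both", {
  set.seed(14)
  img1 <- array(runif(12 * 12 * 3), c(12, 12, 3))
  img2 <- array(runif(12 * 12 * 3), c(12, 12, 3))

  # same seed -> identical choice and parameters
  set.seed(100); a1 <- augment_pair(img1, img2)
  set.seed(100); a2 <- augment_pair(img1, img2)
  expect_identical(a1$transform, a2$transform)
  expect_identical(a1$before, a2$before)

  # horizontal flip is an involution and hits both images
  tf <- list(name = "hflip", params = list())
  once <- augment_pair(img1, img2, transform = tf)
  twice <- augment_pair(once$before, once$after, transform = tf)
  expect_equal(twice$before, img1)
  expect_equal(twice$after, img2)
  expect_false(identical(once$after, img2))

  # every transform preserves the image size
  for (nm in mealintake:::.augmentation_names) {
    set.seed(15)
    tf <- select_augmentation()
    tf$name <- nm
    if (nm == "rotate") tf$params <- list(angle = 10)
    if (nm == "pad") tf$params <- list(frac = 0.08)
    if (nm == "blur") tf$params <- list(sigma = 1)
    if (nm == "sharpen") tf$params <- list(amount = 1)
    if (nm == "contrast") tf$params <- list(factor = 1.2)
    out <- augment_pair(img1, img2, transform = tf)
    expect_equal(dim(out$before), dim(img1))
    expect_equal(dim(out$after), dim(img2))
  }
  expect_error(augment_pair(img1, img2[1:10, , ]), "same size")
})

test_that("each of the seven transforms is drawn near 1/7 of the time", {
  set.seed(16)
  draws <- vapply(seq_len(70000), function(i) select_augmentation()$name,
                  character(1))
  freq <- table(factor(draws, levels = mealintake:::.augmentation_names)) / 70000
  expect_true(all(freq >= 0.13 & freq <= 0.156))
})

test_that("folds partition the data at the planned ratios", {
  tab <- random_table(20)
  folds <- make_folds(tab, fold_plan(), seed = 3)
  expect_length(folds, 10L)
  expect_true(all(vapply(folds, function(f) length(f$test_ids), numeric(1)) == 2))
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(all_test, tab$pair_id)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$val_ids), 0L)
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    expect_length(intersect(f$val_ids, f$test_ids), 0L)
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), tab$pair_id)
  }
  expect_error(make_folds(random_table(5), fold_plan()), "exceeds")
})

test_that("stratification spreads large categories over the test folds", {
  tab <- ref_fixture_table()
  folds <- make_folds(tab, fold_plan(), seed = 4)
  # category 2 has 78 members: every fold's test set should hold some
  cat2 <- tab$pair_id[tab$food_id == 2]
  per_fold <- vapply(folds, function(f) length(intersect(f$test_ids, cat2)),
                     numeric(1))
  expect_true(all(per_fold >= floor(78 / 10) - 1))
})

test_that("early stopping halts after patience stagnant epochs", {
  cfgp <- train_config(patience = 20, max_epochs = 100, seed = 1)
  res <- train(static_val_model(0.5), config = cfgp)
  h <- res$history
  expect_equal(attr(h, "stopped_epoch"), 21L)  # patience + 1
  expect_equal(attr(h, "best_epoch"), 1L)

  # improvement resets the counter; stop comes patience epochs after best
  seq_loss <- c(1, 0.9, 0.8, rep(0.8, 50))
  res2 <- train(static_val_model(seq_loss),
                config = train_config(patience = 5, max_epochs = 100))
  expect_equal(attr(res2$history, "best_epoch"), 3L)
  expect_equal(attr(res2$history, "stopped_epoch"), 8L)
  expect_lte(attr(res2$history, "stopped_epoch") -
               attr(res2$history, "best_epoch"), 5L)
})

test_that("training on easy synthetic data reduces validation error", {
  ds <- tiny_dataset(n_categories = 3, pairs = 12, seed = 6, image_size = 32)
  folds <- make_folds(ds$table, fold_plan(k = 4, train_ratio = 0.5,
                                          val_ratio = 0.25, test_ratio = 0.25),
                      seed = 6)
  cfg <- model_config(backbone_spec("tiny-test", per_image_feature_dim = 24,
                                    input_size = 32),
                      architecture = "MT", n_categories = 3,
                      fc1_out = 24, fc2_out = 12)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 8, batch_size = 8,
                     augment = FALSE, seed = 6, patience = 20)
  m <- build_model(cfg, seed = 6)
  res <- train(m, ds, folds[[1]], tc)
  h <- res$history
  expect_lt(h$val_mae[nrow(h)], h$val_mae[1])
  expect_true(all(diff(h$epoch) == 1))

  # seeded determinism: identical history on a re-run
  m2 <- build_model(cfg, seed = 6)
  res2 <- train(m2, ds, folds[[1]], tc)
  expect_equal(res2$history, res$history, tolerance = 1e-12)

  # history serializes
  path <- withr::local_tempfile(fileext = ".csv")
  write_history(res, path)
  expect_equal(nrow(read.csv(path)), nrow(h))

  # config errors
  empty_split <- folds[[1]]
  empty_split$val_ids <- character(0)
  expect_error(train(build_model(cfg, seed = 1), ds, empty_split, tc), "empty")
})

test_that("augmented training keeps the pairing and still runs", {
  ds <- tiny_dataset(n_categories = 2, pairs = 6, seed = 8, image_size = 32)
  folds <- make_folds(ds$table, fold_plan(k = 3, train_ratio = 0.4,
                                          val_ratio = 0.3, test_ratio = 0.3),
                      seed = 8)
  cfg <- model_config(backbone_spec("tiny-test", per_image_feature_dim = 12,
                                    input_size = 32),
                      architecture = "ST", n_categories = 2,
                      fc1_out = 8, fc2_out = 4)
  tc <- train_config(learning_rate = 1e-3, max_epochs = 2, batch_size = 4,
                     augment = TRUE, seed = 8)
  res <- train(build_model(cfg, seed = 8), ds, folds[[1]], tc)
  expect_equal(nrow(res$history), 2L)
  expect_true(all(is.finite(res$history$val_mae)))
})
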