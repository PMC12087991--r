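test_that("MAE matches an element-wise oracle", {
  expect_equal(mae(c(0.5, 0.5), c(0.5, 0.5)), 0.0)
  expect_equal(mae(c(0.5, 0.5), c(0.4, 0.7)), 0.15)
  set.seed(21)
  p <- runif(100); t <- runif(100)
  oracle <- sum(abs(p - t)) / 100
  expect_equal(mae(p, t), oracle, tolerance = 1e-12)
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
  expect_error(mae(1:3 / 10, 1:2 / 10), "equal-length")
})

test_that("class-wise MAE partitions the overall MAE", {
  p <- c(0.5, 0.5, 0.9)
  t <- c(0.4, 0.6, 0.6)
  out <- classwise_mae(p, t, c(1L, 1L, 2L))
  expect_equal(out, c("1" = 0.1, "2" = 0.3))

  # single category: equals overall MAE
  expect_equal(unname(classwise_mae(p, t, c(3L, 3L, 3L))["3"]), mae(p, t))

  # count-weighted average of class-wise MAEs equals the overall MAE
  set.seed(22)
  n <- 200
  p <- runif(n); t <- runif(n); ids <- sample.int(10, n, replace = TRUE)
  cw <- classwise_mae(p, t, ids)
  counts <- table(ids)[names(cw)]
  expect_equal(sum(cw * as.numeric(counts)) / n, mae(p, t),
               tolerance = 1e-12)
  expect_error(classwise_mae(p, t, rep(99L, n)), "unknown food_id")
})

test_that("classification accuracy counts exact matches", {
  expect_equal(classification_accuracy(1:4, 1:4), 1.0)
  expect_equal(classification_accuracy(c(1, 9, 9, 9), c(1, 2, 3, 4)), 0.25)
  set.seed(23)
  pred <- sample.int(34, 10000, replace = TRUE)
  truth <- sample.int(34, 10000, replace = TRUE)
  acc <- classification_accuracy(pred, truth)
  expect_gte(acc, 0.02)  # chance is ~1/34
  expect_lte(acc, 0.04)
  expect_error(classification_accuracy(integer(0), integer(0)), "non-empty")
})

test_that("human baseline scores levels against scale-derived fractions", {
  tab <- annotation_table(data.frame(
    pair_id = c("a", "b"), food_id = c(1L, 2L),
    weight_before_g = c(100, 700), weight_after_g = c(0, 600),
    observer_level = c(7L, 1L)))
  expect_equal(human_baseline_mae(tab), 0.0)

  tab2 <- annotation_table(data.frame(
    pair_id = "c", food_id = 1L, weight_before_g = 100,
    weight_after_g = 50, observer_level = 4L))
  expect_equal(human_baseline_mae(tab2), abs(4 / 7 - 0.5), tolerance = 1e-12)

  # anchor-exact fixture scores zero
  expect_equal(human_baseline_mae(ref_fixture_table()), 0.0, tolerance = 1e-12)

  # record-by-record oracle on random data
  rt <- random_table(200)
  oracle <- mean(vapply(seq_len(200), function(i) {
    abs(rt$observer_level[i] / 7 -
          (rt$weight_before_g[i] - rt$weight_after_g[i]) / rt$weight_before_g[i])
  }, numeric(1)))
  expect_equal(human_baseline_mae(rt), oracle, tolerance = 1e-12)
})

test_that("level-weight statistics recover dispersion and correlation", {
  # perfectly linear level -> fraction relation
  tab <- ref_fixture_table()
  st <- level_weight_stats(tab)
  expect_equal(st$pearson_r, 1.0, tolerance = 1e-12)
  expect_true(all(st$per_level$sd_eaten < 1e-12))
  expect_equal(st$per_level$mean_leftover, 1 - st$per_level$level / 7,
               tolerance = 1e-12)

  # closed-form correlation oracle on noisy data
  tabj <- ref_fixture_table(jitter_sd = 0.1)
  stj <- level_weight_stats(tabj)
  f <- compute_eaten_fraction(tabj$weight_before_g, tabj$weight_after_g)
  l <- tabj$observer_level
  r_oracle <- sum((l - mean(l)) * (f - mean(f))) /
    sqrt(sum((l - mean(l))^2) * sum((f - mean(f))^2))
  expect_equal(stj$pearson_r, r_oracle, tolerance = 1e-9)
  expect_gt(stj$pearson_r, 0.9)

  const <- annotation_table(data.frame(
    pair_id = c("a", "b"), food_id = 1L, weight_before_g = 100,
    weight_after_g = 50, observer_level = 4L))
  expect_error(level_weight_stats(const), "correlation undefined")
})

test_that("cross-validated evaluation aggregates reference models exactly", {
  tab <- random_table(60, seed = 30)
  ds <- structure(list(table = tab, images = NULL), class = "intake_dataset")
  folds <- make_folds(tab, fold_plan(), seed = 30)

  rep_oracle <- cross_validated_evaluate(function(fold) oracle_model(),
                                         ds, folds)
  expect_equal(rep_oracle$mae, 0.0)
  expect_equal(rep_oracle$mae_sd_over_folds, 0.0)
  expect_equal(rep_oracle$accuracy, 1.0)
  expect_equal(rep_oracle$accuracy_sd_over_folds, 0.0)
  expect_equal(rep_oracle$n_evaluated, 60L)

  # predict-global-mean: per-fold MAE equals the closed-form deviation
  truth_of <- function(ids) {
    df <- tab[match(ids, tab$pair_id), ]
    compute_eaten_fraction(df$weight_before_g, df$weight_after_g)
  }
  factory <- function(fold) global_mean_model(mean(truth_of(fold$train_ids)))
  rep_gm <- cross_validated_evaluate(factory, ds, folds)
  expected <- mean(vapply(folds, function(fold) {
    mean(abs(truth_of(fold$test_ids) - mean(truth_of(fold$train_ids))))
  }, numeric(1)))
  expect_equal(rep_gm$mae, expected, tolerance = 1e-12)
  expect_true(is.na(rep_gm$accuracy))

  # weighted class-wise identity on pooled predictions
  cw <- rep_gm$per_food_mae
  counts <- table(tab$food_id)[names(cw)]
  expect_equal(sum(cw * as.numeric(counts)) / 60, mean(rep_gm$per_fold$mae *
    rep_gm$per_fold$n_test) * 10 / 60, tolerance = 1e-12)
})

test_that("metrics reports serialize to the documented JSON and back", {
  tab <- random_table(40, seed = 31)
  ds <- structure(list(table = tab, images = NULL), class = "intake_dataset")
  folds <- make_folds(tab, fold_plan(), seed = 31)
  report <- cross_validated_evaluate(function(fold) oracle_model(), ds, folds)
  path <- withr::local_tempfile(fileext = ".json")
  metrics_report_json(report, path)
  back <- metrics_report_from_json(path)
  expect_equal(back$mae, report$mae)
  expect_equal(back$accuracy, report$accuracy)
  expect_equal(back$per_food_mae, report$per_food_mae)
  expect_equal(back$n_evaluated, report$n_evaluated)
})
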