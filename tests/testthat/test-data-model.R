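test_that("eaten fraction arithmetic, clamping and scale invariance", {
  expect_equal(compute_eaten_fraction(100, 30), 0.7)
  expect_equal(compute_eaten_fraction(100, 100), 0.0)
  expect_equal(compute_eaten_fraction(100, 0), 1.0)

  expect_error(compute_eaten_fraction(0, 10), "invalid record")
  expect_error(compute_eaten_fraction(-5, 1), "invalid record")
  expect_error(compute_eaten_fraction(100, -1), "weight_after")
  expect_error(compute_eaten_fraction(100, 101, clamp = FALSE),
               "inconsistent weights")
  expect_warning(f <- compute_eaten_fraction(100, 101, clamp = TRUE),
                 "clamped")
  expect_equal(f, 0)

  set.seed(2)
  for (i in 1:25) {
    wb <- runif(1, 1, 500)
    wa <- runif(1, 0, wb)
    ck <- runif(1, 0.01, 50)
    expect_equal(compute_eaten_fraction(wb, wa),
                 compute_eaten_fraction(ck * wb, ck * wa))
  }
})

test_that("observer level maps to level/7 and is strictly increasing", {
  expect_equal(observer_level_to_fraction(7), 1.0)
  expect_equal(observer_level_to_fraction(1), 1 / 7)
  expect_equal(observer_level_to_fraction(1:7), (1:7) / 7)
  expect_true(all(diff(observer_level_to_fraction(1:7)) > 0))
  expect_error(observer_level_to_fraction(0), "invalid level")
  expect_error(observer_level_to_fraction(8), "invalid level")
  expect_error(observer_level_to_fraction(2.5), "invalid level")
})

test_that("annotation CSV round-trips field-for-field", {
  tab <- random_table(30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(tab, path)
  back <- read_annotations(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))

  # empty table -> header-only file
  empty <- annotation_table(tab[0, ])
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(empty, p2)
  expect_length(readLines(p2), 1L)
  expect_equal(nrow(read_annotations(p2)), 0L)
})

test_that("invalid rows and schemas are rejected with row context", {
  tab <- random_table(3)
  df <- as.data.frame(tab)
  df$observer_level[2] <- 8L
  expect_error(annotation_table(df), "row 2")

  df2 <- as.data.frame(tab)
  df2$pair_id[2] <- df2$pair_id[1]
  expect_error(annotation_table(df2), "unique")
  expect_error(write_annotations(structure(df2, catalog = food_catalog()),
                                 tempfile()), "unique")

  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(tab, path)
  raw <- read.csv(path, colClasses = "character")
  raw$weight_before_g <- NULL
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, p3, row.names = FALSE)
  expect_error(read_annotations(p3), "schema error")

  raw2 <- read.csv(path, colClasses = "character")
  raw2$weight_after_g[3] <- "abc"
  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw2, p4, row.names = FALSE)
  expect_error(read_annotations(p4), "row 3")
})

test_that("a layout mapping adapts foreign column names", {
  tab <- random_table(5)
  df <- as.data.frame(tab)
  names(df)[names(df) == "weight_before_g"] <- "w_start"
  names(df)[names(df) == "weight_after_g"] <- "w_end"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_annotations(path, layout = c(weight_before_g = "w_start",
                                            weight_after_g = "w_end"))
  expect_equal(back$weight_before_g, tab$weight_before_g, tolerance = 1e-9)
})

test_that("validate_dataset reports counts, missing files and violations", {
  tab <- ref_fixture_table()
  rep <- validate_dataset(NULL, tab)
  expect_equal(rep$total_pairs, 524L)
  expect_equal(sum(rep$per_category > 0), 34L)
  expect_equal(sum(rep$per_category), rep$total_pairs)
  expect_equal(sum(rep$per_level), rep$total_pairs)
  expect_length(rep$violations, 0L)

  # empty dataset
  rep0 <- validate_dataset(withr::local_tempdir(), tab[0, ])
  expect_equal(rep0$total_pairs, 0L)
  expect_length(rep0$violations, 0L)

  # one record pointing at a missing image is reported, not thrown
  root <- withr::local_tempdir()
  df <- as.data.frame(random_table(2))
  df$before_image[1] <- "images/nothere.png"
  repm <- validate_dataset(root, df)
  expect_equal(repm$missing_files, df$pair_id[1])

  # invariant violations in a raw data frame are reported
  df$observer_level[2] <- 9L
  repv <- validate_dataset(root, df)
  expect_true(any(grepl("observer_level", repv$violations)))

  js <- validation_report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$total_pairs, 524L)
})
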