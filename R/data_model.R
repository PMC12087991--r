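# Annotation data model: one record per before/after image pair with the
# scale weights (grams), the observer's 1-7 leftover level, and image paths.

.annotation_cols <- c("pair_id", "food_id", "food_name", "weight_before_g",
                      "weight_after_g", "observer_level", "before_image",
                      "after_image")

#' Eaten fraction from scale weights
#'
#' The regression target: `(weight_before - weight_after) / weight_before`,
#' the dimensionless fraction of the served meal that was consumed.
#' Real scales can report `weight_after` marginally above `weight_before`
#' (condensation, tray handling); with `clamp = TRUE` (default) such
#' fractions are clamped to 0 with a warning, otherwise they are an error.
#'
#' @param weight_before,weight_after Weights in grams; `weight_before > 0`,
#'   `weight_after >= 0`. Vectorized.
#' @param clamp Clamp negative fractions to 0 (with a warning) instead of
#'   erroring.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' compute_eaten_fraction(100, 30)  # 0.7
#' @export
compute_eaten_fraction <- function(weight_before, weight_after, clamp = TRUE) {
  weight_before <- as.numeric(weight_before)
  weight_after <- as.numeric(weight_after)
  if (length(weight_before) != length(weight_after)) {
    stop("weight vectors must have equal length", call. = FALSE)
  }
  if (anyNA(weight_before) || anyNA(weight_after) || any(weight_before <= 0)) {
    stop("invalid record: weight_before must be > 0 and weights non-missing",
         call. = FALSE)
  }
  if (any(weight_after < 0)) {
    stop("invalid record: weight_after must be >= 0", call. = FALSE)
  }
  f <- (weight_before - weight_after) / weight_before
  neg <- f < 0
  if (any(neg)) {
    if (!clamp) {
      stop("inconsistent weights: weight_after exceeds weight_before",
           call. = FALSE)
    }
    warning(sum(neg), " record(s) with weight_after > weight_before; ",
            "eaten fraction clamped to 0", call. = FALSE)
    f[neg] <- 0
  }
  f
}

#' Observer level to eaten fraction
#'
#' Maps the ordinal visual leftover level (1 = not consumed at all,
#' 7 = zero remaining) to the eaten-fraction scale as `level / 7`, the
#' convention used to score the human-observer baseline.
#'
#' @param level Integer vector with values in 1..7.
#' @return Numeric vector of fractions (`1/7`, ..., `1`).
#' @export
observer_level_to_fraction <- function(level) {
  if (length(level) == 0 || anyNA(level) || any(level != as.integer(level)) ||
      any(level < 1) || any(level > 7)) {
    stop("invalid level: observer levels must be integers in 1..7",
         call. = FALSE)
  }
  as.integer(level) / 7
}

#' Build an annotation table
#'
#' Bundles pair records with their food catalog and enforces the record
#' invariants: unique `pair_id`, `food_id` present in the catalog,
#' `observer_level` in 1..7, positive `weight_before_g`, and (after the
#' clamping policy) `weight_after_g <= weight_before_g`.
#'
#' @param records Data frame with columns `pair_id`, `food_id`,
#'   `weight_before_g`, `weight_after_g`, `observer_level`, and optionally
#'   `food_name`, `before_image`, `after_image` (empty string = no image).
#' @param catalog A [food_catalog()].
#' @param clamp_weights Clamp `weight_after_g` down to `weight_before_g`
#'   (with a warning) instead of erroring.
#' @return An `annotation_table` (data frame, catalog attached as attribute).
#' @export
annotation_table <- function(records, catalog = food_catalog(),
                             clamp_weights = TRUE) {
  catalog <- if (inherits(catalog, "food_catalog")) catalog else food_catalog(catalog)
  req <- c("pair_id", "food_id", "weight_before_g", "weight_after_g",
           "observer_level")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  df$pair_id <- as.character(df$pair_id)
  df$food_id <- as.integer(df$food_id)
  df$weight_before_g <- as.numeric(df$weight_before_g)
  df$weight_after_g <- as.numeric(df$weight_after_g)
  df$observer_level <- as.integer(df$observer_level)
  for (col in c("before_image", "after_image")) {
    if (is.null(df[[col]])) df[[col]] <- ""
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  }
  df$food_name <- catalog$food_name[df$food_id]

  .row_fail <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      i <- which(bad | is.na(bad))[1]
      stop("row ", i, " (pair_id ", df$pair_id[i], "): ", what, call. = FALSE)
    }
  }
  if (anyDuplicated(df$pair_id)) {
    stop("pair_id values must be unique", call. = FALSE)
  }
  .row_fail(is.na(df$food_id) | df$food_id < 1 |
              df$food_id > nrow(catalog), "food_id not in catalog")
  .row_fail(is.na(df$observer_level) | df$observer_level < 1 |
              df$observer_level > 7, "observer_level outside 1..7")
  .row_fail(is.na(df$weight_before_g) | df$weight_before_g <= 0,
            "weight_before_g must be > 0")
  .row_fail(is.na(df$weight_after_g) | df$weight_after_g < 0,
            "weight_after_g must be >= 0")
  over <- df$weight_after_g > df$weight_before_g
  if (any(over)) {
    if (!clamp_weights) .row_fail(over, "weight_after_g exceeds weight_before_g")
    warning(sum(over), " record(s) with weight_after_g > weight_before_g ",
            "clamped to weight_before_g", call. = FALSE)
    df$weight_after_g[over] <- df$weight_before_g[over]
  }
  df <- df[, .annotation_cols]
  rownames(df) <- NULL
  attr(df, "catalog") <- catalog
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("<annotation_table> ", nrow(x), " pair(s), ",
      length(unique(x$food_id)), " categor(ies)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more row(s)\n", sep = "")
  invisible(x)
}

#' Read an annotation table from CSV
#'
#' The documented layout is a UTF-8 CSV with header
#' `pair_id,food_id,food_name,weight_before_g,weight_after_g,observer_level,before_image,after_image`.
#' A `layout` mapping adapts foreign column names (e.g. a deposited dataset's
#' own spreadsheet) to this schema.
#'
#' @param source Path to a CSV file.
#' @param layout Optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(weight_before_g = "w_before")`. Unmapped names are used as-is.
#' @param catalog Catalog used to validate `food_id`.
#' @param clamp_weights Passed to [annotation_table()].
#' @return An [annotation_table()].
#' @export
read_annotations <- function(source, layout = NULL, catalog = food_catalog(),
                             clamp_weights = TRUE) {
  if (!file.exists(source)) {
    stop("annotation file not found: ", source, call. = FALSE)
  }
  raw <- read.csv(source, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  wanted <- setdiff(.annotation_cols, "food_name")
  src_names <- setNames(wanted, wanted)
  if (!is.null(layout)) src_names[names(layout)] <- layout
  miss <- setdiff(src_names[setdiff(wanted, c("before_image", "after_image"))],
                  names(raw))
  if (length(miss)) {
    stop("schema error: column(s) ", paste(miss, collapse = ", "),
         " not present in ", source, call. = FALSE)
  }
  df <- data.frame(pair_id = raw[[src_names["pair_id"]]],
                   stringsAsFactors = FALSE)
  for (col in c("food_id", "observer_level")) {
    v <- suppressWarnings(as.integer(raw[[src_names[col]]]))
    bad <- is.na(v) & !is.na(raw[[src_names[col]]])
    if (any(bad)) {
      stop("row ", which(bad)[1], ": cannot parse ", col, " value '",
           raw[[src_names[col]]][which(bad)[1]], "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  for (col in c("weight_before_g", "weight_after_g")) {
    v <- suppressWarnings(as.numeric(raw[[src_names[col]]]))
    bad <- is.na(v) & !is.na(raw[[src_names[col]]])
    if (any(bad)) {
      stop("row ", which(bad)[1], ": cannot parse ", col, " value '",
           raw[[src_names[col]]][which(bad)[1]], "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  for (col in c("before_image", "after_image")) {
    df[[col]] <- if (src_names[col] %in% names(raw)) raw[[src_names[col]]] else ""
  }
  annotation_table(df, catalog = catalog, clamp_weights = clamp_weights)
}

#' Write an annotation table to CSV
#'
#' Emits the documented column layout; [read_annotations()] on the result
#' reproduces the table field-for-field.
#'
#' @param table An [annotation_table()] (invariants are re-checked first).
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
write_annotations <- function(table, destination) {
  table <- annotation_table(table, catalog = attr(table, "catalog") %||% food_catalog())
  dir.create(dirname(destination), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(table)[, .annotation_cols]
  # %.17g: shortest-exact decimal, so round-trips are lossless and equal
  # tables serialize to identical bytes
  df$weight_before_g <- sprintf("%.17g", df$weight_before_g)
  df$weight_after_g <- sprintf("%.17g", df$weight_after_g)
  write.csv(df, destination, row.names = FALSE, quote = TRUE, eol = "\n",
            fileEncoding = "UTF-8")
  invisible(destination)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a dataset directory against its annotation table
#'
#' All problems are reported, never thrown: the report lists the total pair
#' count, per-category and per-level counts, records whose referenced image
#' files are missing under `root`, and invariant violations. Records with an
#' empty image reference are treated as annotation-only and skipped by the
#' file check.
#'
#' @param root Dataset directory that image paths are relative to (may be
#'   `NULL` to skip file checks).
#' @param table An [annotation_table()] or a plain data frame in the same
#'   layout (plain data frames may carry violations, which get reported).
#' @param catalog Catalog used for the category check.
#' @return A `validation_report` list with elements `total_pairs`,
#'   `per_category`, `per_level`, `missing_files`, `violations`.
#' @export
validate_dataset <- function(root, table, catalog = food_catalog()) {
  catalog <- if (inherits(catalog, "food_catalog")) catalog else food_catalog(catalog)
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  violations <- character()
  n <- nrow(df)
  if (n > 0 && anyDuplicated(df$pair_id)) {
    violations <- c(violations, paste0("duplicate pair_id: ",
      paste(unique(df$pair_id[duplicated(df$pair_id)]), collapse = ", ")))
  }
  chk <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      ids <- df$pair_id[which(bad | is.na(bad))]
      violations <<- c(violations,
                       paste0(what, ": ", paste(ids, collapse = ", ")))
    }
  }
  if (n > 0) {
    chk(is.na(df$food_id) | df$food_id < 1 | df$food_id > nrow(catalog),
        "food_id not in catalog")
    chk(is.na(df$observer_level) | df$observer_level < 1 | df$observer_level > 7,
        "observer_level outside 1..7")
    chk(is.na(df$weight_before_g) | df$weight_before_g <= 0,
        "non-positive weight_before_g")
    chk(!is.na(df$weight_before_g) & !is.na(df$weight_after_g) &
          (df$weight_after_g > df$weight_before_g | df$weight_after_g < 0),
        "inconsistent weights")
  }
  missing_files <- character()
  if (!is.null(root) && n > 0) {
    for (col in c("before_image", "after_image")) {
      ref <- df[[col]] %||% rep("", n)
      has <- !is.na(ref) & nzchar(ref)
      bad <- has & !file.exists(file.path(root, ref))
      missing_files <- c(missing_files, df$pair_id[bad])
    }
    missing_files <- sort(unique(missing_files))
  }
  per_category <- integer(0)
  per_level <- integer(0)
  if (n > 0) {
    tc <- table(factor(df$food_id, levels = catalog$food_id))
    per_category <- setNames(as.integer(tc), names(tc))
    tl <- table(factor(df$observer_level, levels = 1:7))
    per_level <- setNames(as.integer(tl), names(tl))
  }
  rep <- list(total_pairs = n,
              per_category = per_category,
              per_level = per_level,
              missing_files = missing_files,
              violations = violations)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n",
      "  total pairs:   ", x$total_pairs, "\n",
      "  categories:    ", sum(x$per_category > 0), "\n",
      "  missing files: ", length(x$missing_files), "\n",
      "  violations:    ", length(x$violations), "\n", sep = "")
  if (length(x$violations)) cat(paste0("  - ", x$violations, "\n"), sep = "")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A [validate_dataset()] result.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
validation_report_json <- function(report, path = NULL) {
  obj <- list(total_pairs = report$total_pairs,
              per_category = as.list(report$per_category),
              per_level = as.list(report$per_level),
              missing_files = report$missing_files,
              violations = report$violations)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
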