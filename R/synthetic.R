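# Synthetic plate scenes: a white plate on a black/white 2x2 cm checkerboard
# placemat, carrying a coloured food region whose rendered area shrinks by a
# known eaten fraction between the "before" and "after" image of a pair.
# Weight ground truth is defined from rendered area (grams = density * cm^2),
# so the whole pipeline is testable closed-loop.

#' Scene configuration for the synthetic simulator
#'
#' @param image_size Square image side in pixels.
#' @param px_per_cm Rendering scale; the default frames 24 cm of placemat.
#' @param checker_cm Checkerboard grid size in cm (2 cm in the emulated rig).
#' @param plate_radius_cm Plate radius in cm; the plate must fit the image.
#' @param lighting_jitter Relative amplitude in `[0, 1)` of a per-pair
#'   multiplicative brightness factor (identical in both images of a pair,
#'   emulating a fixed rig with slight exposure drift between pairs).
#' @param oil_residue_prob Probability that the after image keeps a faint
#'   translucent oil film over the food's original footprint without a
#'   material weight change (the known failure mode of appearance-based
#'   leftover estimation on oily dishes).
#' @param oil_opacity Opacity of that film in `[0, 1]` (free parameter; the
#'   emulated effect is qualitative).
#' @param density Grams of food per cm^2 of rendered area.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = 128, px_per_cm = image_size / 24,
                         checker_cm = 2, plate_radius_cm = 9,
                         lighting_jitter = 0.05, oil_residue_prob = 0.1,
                         oil_opacity = 0.15, density = 1.3) {
  stopifnot(image_size >= 16, px_per_cm > 0, checker_cm > 0,
            plate_radius_cm > 0, lighting_jitter >= 0, lighting_jitter < 1,
            oil_residue_prob >= 0, oil_residue_prob <= 1,
            oil_opacity >= 0, oil_opacity <= 1, density > 0)
  if (2 * plate_radius_cm * px_per_cm > image_size) {
    stop("plate does not fit inside the image", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), px_per_cm = px_per_cm,
                 checker_cm = checker_cm, plate_radius_cm = plate_radius_cm,
                 lighting_jitter = lighting_jitter,
                 oil_residue_prob = oil_residue_prob,
                 oil_opacity = oil_opacity, density = density),
            class = "scene_config")
}

#' Visual style of a food category
#'
#' Distinct categories receive distinct hue/shape combinations so that a
#' classifier has a visual signal to learn, loosely emulating the colour and
#' shape diversity of real hospital dishes.
#'
#' @param category_id Integer category id.
#' @param hue Hue in degrees (0--360).
#' @param shape One of `"disk"`, `"ellipse"`, `"blob-cluster"`.
#' @param texture_seed Integer seed of the deterministic texture pattern.
#' @return A `food_style` list.
#' @export
food_style <- function(category_id, hue, shape = c("disk", "ellipse", "blob-cluster"),
                       texture_seed = category_id) {
  shape <- match.arg(shape)
  structure(list(category_id = as.integer(category_id), hue = hue %% 360,
                 shape = shape, texture_seed = as.integer(texture_seed)),
            class = "food_style")
}

#' Default style set for the first `n` categories
#'
#' Hues are spread by the golden angle and shapes cycle through the three
#' primitives, so all pairs of categories differ in hue and most also in
#' shape.
#'
#' @param n Number of categories (at most the catalog's 34).
#' @return List of [food_style()] objects.
#' @export
default_styles <- function(n) {
  stopifnot(n >= 1, n <= 34)
  shapes <- c("disk", "ellipse", "blob-cluster")
  lapply(seq_len(n), function(i) {
    food_style(i, hue = (20 + (i - 1) * 137.508) %% 360,
               shape = shapes[(i - 1) %% 3 + 1], texture_seed = 1000 + i)
  })
}

#' Generation plan for a synthetic dataset
#'
#' @param n_categories Number of categories to simulate (<= 34).
#' @param pairs_per_category Image pairs per category.
#' @param eaten_fraction_distribution Currently `"uniform"` on `[0, 1]`.
#' @param level_noise_sd Gaussian noise SD on the fraction the simulated
#'   observer perceives at mid-range fractions.
#' @param level_noise_sd_extreme The smaller SD used near empty/full plates,
#'   where real observers are more certain.
#' @param size_jitter Relative spread of portion size around the category
#'   base portion.
#' @param seed Integer seed making generation fully deterministic.
#' @return A `generation_spec` list.
#' @export
generation_spec <- function(n_categories = 8, pairs_per_category = 50,
                            eaten_fraction_distribution = "uniform",
                            level_noise_sd = 0.15,
                            level_noise_sd_extreme = 0.10,
                            size_jitter = 0.15, seed = 1) {
  stopifnot(n_categories >= 1, n_categories <= 34, pairs_per_category >= 1,
            level_noise_sd >= 0, level_noise_sd_extreme >= 0,
            size_jitter >= 0, size_jitter < 1)
  eaten_fraction_distribution <- match.arg(eaten_fraction_distribution, "uniform")
  structure(list(n_categories = as.integer(n_categories),
                 pairs_per_category = as.integer(pairs_per_category),
                 eaten_fraction_distribution = eaten_fraction_distribution,
                 level_noise_sd = level_noise_sd,
                 level_noise_sd_extreme = level_noise_sd_extreme,
                 size_jitter = size_jitter, seed = as.integer(seed)),
            class = "generation_spec")
}

# deterministic multiplicative texture in [1-amp, 1+amp], from pixel coords
.texture_field <- function(xs_cm, ys_cm, seed, amp = 0.12) {
  ph <- (seed * c(0.618034, 0.414214, 0.732051)) %% 1 * 2 * pi
  g <- outer(ys_cm, xs_cm, function(y, x) {
    sin(2.2 * x + 3.1 * y + ph[1]) + sin(5.3 * x - 2.7 * y + ph[2]) +
      sin(1.3 * x * y + ph[3])
  })
  1 + amp * g / 3
}

.hsv_rgb <- function(h, s, v) {
  grDevices::col2rgb(grDevices::hsv(h / 360, s, v))[, 1] / 255
}

# Soft (anti-aliased) coverage in [0,1] of the food region; `geom` holds the
# component positions/radii in cm relative to the food centroid.
.food_coverage <- function(scene, geom, scale) {
  n <- scene$image_size
  ctr_px <- (seq_len(n) - 0.5) / scene$px_per_cm  # pixel centers in cm
  xs <- ctr_px - geom$cx
  ys <- ctr_px - geom$cy
  d_cm <- matrix(-Inf, n, n)
  for (comp in geom$components) {
    a <- comp$a * scale
    b <- comp$b * scale
    dx <- outer(rep(1, n), xs - comp$dx * scale)
    dy <- outer(ys - comp$dy * scale, rep(1, n))
    if (comp$theta != 0) {
      co <- cos(comp$theta); si <- sin(comp$theta)
      rx <- dx * co + dy * si
      ry <- -dx * si + dy * co
    } else {
      rx <- dx; ry <- dy
    }
    # signed inside-distance, approximated for ellipses by scaled radius
    d <- (1 - sqrt((rx / a)^2 + (ry / b)^2)) * min(a, b)
    d_cm <- pmax(d_cm, d)
  }
  pmin(pmax(d_cm * scene$px_per_cm + 0.5, 0), 1)
}

# food geometry (component layout) drawn once per pair, in cm
.draw_geometry <- function(style, scene) {
  base_r <- 0.5 * scene$plate_radius_cm  # base portion radius
  size <- base_r * runif(1, 0.85, 1.15)
  max_off <- scene$plate_radius_cm - 1.6 * size
  off <- if (max_off > 0) runif(2, -0.5, 0.5) * max_off else c(0, 0)
  half <- scene$image_size / scene$px_per_cm / 2
  geom <- list(cx = half + off[1], cy = half + off[2])
  if (style$shape == "disk") {
    geom$components <- list(list(dx = 0, dy = 0, a = size, b = size, theta = 0))
  } else if (style$shape == "ellipse") {
    geom$components <- list(list(dx = 0, dy = 0, a = 1.25 * size,
                                 b = 0.72 * size, theta = runif(1, 0, pi)))
  } else {
    k <- 4L
    geom$components <- lapply(seq_len(k), function(i) {
      ang <- 2 * pi * (i - 1) / k + runif(1, -0.4, 0.4)
      r <- runif(1, 0.25, 0.55) * size
      list(dx = r * cos(ang), dy = r * sin(ang),
           a = runif(1, 0.5, 0.65) * size, b = runif(1, 0.5, 0.65) * size,
           theta = 0)
    })
  }
  geom
}

# placemat + plate, identical in both images of a pair
.render_background <- function(scene) {
  n <- scene$image_size
  cm <- (seq_len(n) - 0.5) / scene$px_per_cm
  cell <- outer(floor(cm / scene$checker_cm), floor(cm / scene$checker_cm), "+")
  mat <- ifelse(cell %% 2 == 0, 0.92, 0.06)
  half_cm <- n / scene$px_per_cm / 2
  dist <- sqrt(outer((cm - half_cm)^2, (cm - half_cm)^2, "+"))
  plate <- pmin(pmax((scene$plate_radius_cm - dist) * scene$px_per_cm + 0.5, 0), 1)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- mat * (1 - plate) + 0.97 * plate
  list(img = img, plate = plate)
}

.compose_food <- function(bg_img, cov, color, texture) {
  out <- bg_img
  for (ch in 1:3) {
    out[, , ch] <- bg_img[, , ch] * (1 - cov) +
      pmin(pmax(color[ch] * texture, 0), 1) * cov
  }
  out
}

#' Generate one synthetic before/after pair
#'
#' The before image shows a food region of rendered area `A0`; the after
#' image shows the same scene with the region shrunk around its centroid to
#' area `A1` with `A1/A0 = 1 - eaten_fraction` up to rasterization error.
#' Recorded weights are exact by construction:
#' `weight_before = density * A0` (cm^2) and
#' `weight_after = weight_before * (1 - eaten_fraction)`.
#'
#' Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param style A [food_style()].
#' @param scene A [scene_config()].
#' @param eaten_fraction True eaten fraction in `[0, 1]`.
#' @param pair_id Identifier stored in the returned record.
#' @param observer_level Optional precomputed level; when `NULL` it is drawn
#'   with [assign_observer_level()] using `noise_sd`.
#' @param noise_sd Observer noise SD used when `observer_level` is `NULL`.
#' @return List with elements `record` (one-row data frame), `before`,
#'   `after` (H x W x 3 arrays in `[0, 1]`), and `oil_residue` (flag).
#' @export
generate_pair <- function(style, scene, eaten_fraction, pair_id = "pair0001",
                          observer_level = NULL, noise_sd = 0) {
  if (!is.numeric(eaten_fraction) || length(eaten_fraction) != 1 ||
      is.na(eaten_fraction) || eaten_fraction < 0 || eaten_fraction > 1) {
    stop("eaten_fraction must be a single value in [0, 1]", call. = FALSE)
  }
  bg <- .render_background(scene)
  geom <- .draw_geometry(style, scene)
  cov0 <- .food_coverage(scene, geom, scale = 1)
  scale_after <- sqrt(1 - eaten_fraction)
  cov1 <- if (scale_after > 0) .food_coverage(scene, geom, scale = scale_after)
          else matrix(0, scene$image_size, scene$image_size)

  n <- scene$image_size
  cm <- (seq_len(n) - 0.5) / scene$px_per_cm
  texture <- .texture_field(cm, cm, style$texture_seed)
  color <- .hsv_rgb(style$hue, 0.85, 0.72)

  before <- .compose_food(bg$img, cov0, color, texture)
  after <- .compose_food(bg$img, cov1, color, texture)

  oil <- runif(1) < scene$oil_residue_prob
  if (oil && scene$oil_opacity > 0) {
    film <- cov0 * pmax(1 - cov1, 0) * scene$oil_opacity
    oil_col <- c(0.85, 0.78, 0.45)
    for (ch in 1:3) {
      after[, , ch] <- after[, , ch] * (1 - film) + oil_col[ch] * film
    }
  }
  jit <- 1 + runif(1, -scene$lighting_jitter, scene$lighting_jitter)
  before <- pmin(pmax(before * jit, 0), 1)
  after <- pmin(pmax(after * jit, 0), 1)

  area_cm2 <- sum(cov0) / scene$px_per_cm^2
  weight_before <- scene$density * area_cm2
  weight_after <- weight_before * (1 - eaten_fraction)
  if (is.null(observer_level)) {
    observer_level <- assign_observer_level(eaten_fraction, noise_sd)
  }
  record <- data.frame(pair_id = pair_id, food_id = style$category_id,
                       weight_before_g = weight_before,
                       weight_after_g = weight_after,
                       observer_level = observer_level,
                       before_image = "", after_image = "",
                       stringsAsFactors = FALSE)
  list(record = record, before = before, after = after, oil_residue = oil)
}

#' Simulate the observer's leftover level for a true fraction
#'
#' Adds zero-mean Gaussian noise with the given SD to the fraction, clamps
#' to `[0, 1]`, and returns the level whose anchor value (`level / 7`) is
#' nearest.
#'
#' @param fraction True eaten fraction(s) in `[0, 1]`.
#' @param noise_sd Gaussian noise SD (>= 0); 0 gives the deterministic
#'   nearest-anchor level.
#' @return Integer level(s) in 1..7.
#' @export
assign_observer_level <- function(fraction, noise_sd = 0.15) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  if (any(is.na(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  noisy <- fraction + if (noise_sd > 0) rnorm(length(fraction), 0, noise_sd) else 0
  noisy <- pmin(pmax(noisy, 0), 1)
  anchors <- (1:7) / 7
  vapply(noisy, function(f) which.min(abs(f - anchors)), integer(1))
}

#' Generate a full synthetic dataset on disk
#'
#' Writes `n_categories * pairs_per_category` PNG image pairs under
#' `destination/images/`, the annotation CSV as
#' `destination/annotations.csv`, and a `manifest.json` recording spec,
#' scene and seed. Fully deterministic given the spec's seed.
#'
#' @param spec A [generation_spec()].
#' @param scene A [scene_config()].
#' @param destination Output directory (created if missing).
#' @param write_images Set `FALSE` to keep images in memory only (the
#'   returned table then has empty image references).
#' @return The [annotation_table()]; when `write_images = FALSE` the pair
#'   images are attached as attribute `"images"` (a named list of
#'   `list(before, after)` keyed by `pair_id`).
#' @export
generate_dataset <- function(spec = generation_spec(), scene = scene_config(),
                             destination = NULL, write_images = !is.null(destination)) {
  if (write_images && is.null(destination)) {
    stop("destination required when write_images = TRUE", call. = FALSE)
  }
  set.seed(spec$seed)
  styles <- default_styles(spec$n_categories)
  if (!is.null(destination)) {
    dir.create(file.path(destination, "images"), recursive = TRUE,
               showWarnings = FALSE)
  }
  records <- vector("list", spec$n_categories * spec$pairs_per_category)
  images <- if (!write_images) list() else NULL
  idx <- 0L
  for (style in styles) {
    for (j in seq_len(spec$pairs_per_category)) {
      idx <- idx + 1L
      pid <- sprintf("pair%04d", idx)
      f <- runif(1)
      sd_use <- if (f <= 1.5 / 7 || f >= 6.5 / 7) spec$level_noise_sd_extreme
                else spec$level_noise_sd
      p <- generate_pair(styles[[style$category_id]], scene, f, pair_id = pid,
                         noise_sd = sd_use)
      rec <- p$record
      if (write_images) {
        rec$before_image <- file.path("images", paste0(pid, "_before.png"))
        rec$after_image <- file.path("images", paste0(pid, "_after.png"))
        .write_png(p$before, file.path(destination, rec$before_image))
        .write_png(p$after, file.path(destination, rec$after_image))
      } else {
        images[[pid]] <- list(before = p$before, after = p$after)
      }
      records[[idx]] <- rec
    }
  }
  tab <- annotation_table(do.call(rbind, records),
                          catalog = food_catalog(spec$n_categories))
  if (!is.null(destination)) {
    write_annotations(tab, file.path(destination, "annotations.csv"))
    manifest <- list(spec = unclass(spec),
                     scene = unclass(scene), seed = spec$seed)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(destination, "manifest.json"))
  }
  if (!write_images) attr(tab, "images") <- images
  tab
}

# ---- image array I/O helpers (arrays are [row = y, col = x, channel]) ----

.to_ebi <- function(img) EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")

.from_ebi <- function(e) {
  d <- EBImage::imageData(e)
  if (length(dim(d)) == 2) d <- array(rep(d, 3), c(dim(d), 3))
  aperm(d[, , 1:3, drop = FALSE], c(2, 1, 3))
}

.write_png <- function(img, path) {
  EBImage::writeImage(.to_ebi(img), path, type = "png")
  invisible(path)
}

#' Read an RGB image into the package's array convention
#'
#' @param path PNG or JPEG file.
#' @return H x W x 3 numeric array in `[0, 1]` (rows = image y axis).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  .from_ebi(EBImage::readImage(path))
}
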