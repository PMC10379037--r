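#' RGB image container
#'
#' Wraps an 8-bit RGB image as an `H x W x 3` numeric array with values in
#' `[0, 255]`. Row 1 is the top of the image; column 1 is the left.
#'
#' @param pixels numeric array of dimension `H x W x 3`, values in `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("image must be an H x W x 3 array (got %s)",
          paste(dim(pixels), collapse = " x "))
  if (any(dim(pixels)[1:2] < 1L)) stopf("image has empty dimensions")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("channel values must lie in [0, 255]")
  structure(list(pixels = pixels,
                 height_px = dim(pixels)[1], width_px = dim(pixels)[2]),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d px>\n", x$width_px, x$height_px))
  invisible(x)
}

#' Read an RGB image from disk
#'
#' Loads a JPEG or PNG scan of an olive grid. Images are converted to 8-bit
#' RGB; any alpha channel is dropped and resolution metadata is ignored.
#'
#' @param path path to a JPEG or PNG file.
#' @return An [rgb_image()].
#' @export
read_olive_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L)
    stopf("grayscale image: 3-channel RGB input required (%s)", path)
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(a)[3] != 3L)
    stopf("expected 3 colour channels, found %d (%s)", dim(a)[3], path)
  # EBImage stores [x, y, channel]; transpose to rows x cols
  rgb_image(aperm(a, c(2L, 1L, 3L)) * 255)
}

#' Alveolar grid layout
#'
#' Geometry of the alveolar support tray: olives are fixed in a
#' `n_rows x n_cols` matrix on a uniform background. The two layouts used in
#' practice are 4 x 8 and 4 x 6.
#'
#' @param n_rows,n_cols number of rows / columns of alveoli (>= 1).
#' @return Object of class `grid_layout` with fields `n_rows`, `n_cols`,
#'   `expected_count`.
#' @export
grid_layout <- function(n_rows = 4L, n_cols = 8L) {
  if (!is_count(n_rows) || !is_count(n_cols))
    stopf("n_rows and n_cols must be positive integers")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 expected_count = as.integer(n_rows * n_cols)),
            class = "grid_layout")
}

#' Background-segmentation settings
#'
#' The dark alveolar support has near-zero blue intensity while olive flesh
#' (yellow-green) and stained flesh (fuchsia) both carry appreciable blue, so
#' the blue channel separates foreground from background. A blue support is
#' also supported: there the background has high blue and low red.
#'
#' @param background_threshold_mode `"otsu"` (threshold from the blue-channel
#'   histogram) or `"fixed"`.
#' @param blue_fixed_threshold 8-bit level used when mode is `"fixed"`.
#' @param min_olive_area_px connected components smaller than this are
#'   discarded as debris.
#' @param morphology_radius_px radius of the disc used for morphological
#'   closing of the mask (0 disables closing).
#' @param background_colour `"dark"` (default; low blue is background) or
#'   `"blue"` (high blue and low red is background).
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(background_threshold_mode = c("otsu", "fixed"),
                                blue_fixed_threshold = 40,
                                min_olive_area_px = 200L,
                                morphology_radius_px = 2L,
                                background_colour = c("dark", "blue")) {
  mode <- match.arg(background_threshold_mode)
  bg <- match.arg(background_colour)
  if (!is_num1(blue_fixed_threshold) ||
      blue_fixed_threshold < 0 || blue_fixed_threshold > 255)
    stopf("blue_fixed_threshold must be in [0, 255]")
  if (!is_count(min_olive_area_px)) stopf("min_olive_area_px must be >= 1")
  if (!is.numeric(morphology_radius_px) || morphology_radius_px < 0)
    stopf("morphology_radius_px must be >= 0")
  structure(list(background_threshold_mode = mode,
                 blue_fixed_threshold = blue_fixed_threshold,
                 min_olive_area_px = as.integer(min_olive_area_px),
                 morphology_radius_px = as.integer(morphology_radius_px),
                 background_colour = bg),
            class = "segmentation_config")
}

#' Treated-pixel classifier settings
#'
#' Phenolphthalein turns NaOH-penetrated flesh pink/fuchsia (strong red,
#' suppressed green) while untreated flesh stays yellow-green (green close to
#' or above red). The default classifier thresholds the red-minus-green
#' channel difference; a hue-band mode is available as an alternative.
#'
#' @param mode `"channel_difference"` or `"hue_band"`.
#' @param red_minus_green_min minimum `R - G` for a treated pixel
#'   (channel_difference mode).
#' @param red_min minimum red level for a treated pixel.
#' @param hue_band_deg length-2 numeric, hue interval in degrees
#'   (hue_band mode); may wrap around 360 (e.g. `c(300, 30)`).
#' @param exclude_specular if `TRUE`, saturated white pixels (all channels
#'   >= 250), typically drying highlights, are never counted as treated.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(mode = c("channel_difference", "hue_band"),
                              red_minus_green_min = 40,
                              red_min = 100,
                              hue_band_deg = c(280, 350),
                              exclude_specular = TRUE) {
  mode <- match.arg(mode)
  if (!is_num1(red_minus_green_min) || abs(red_minus_green_min) > 255)
    stopf("red_minus_green_min out of channel range")
  if (!is_num1(red_min) || red_min < 0 || red_min > 255)
    stopf("red_min must be in [0, 255]")
  if (length(hue_band_deg) != 2L || any(hue_band_deg < 0 | hue_band_deg > 360))
    stopf("hue_band_deg must be two angles in [0, 360]")
  structure(list(mode = mode, red_minus_green_min = red_minus_green_min,
                 red_min = red_min, hue_band_deg = hue_band_deg,
                 exclude_specular = isTRUE(exclude_specular)),
            class = "classifier_config")
}

# channel as a matrix even for single-row/column images
channel_matrix <- function(image, ch) {
  matrix(image$pixels[, , ch], nrow = image$height_px)
}

as_rgb_image <- function(image) {
  if (inherits(image, "rgb_image")) return(image)
  if (is.array(image)) return(rgb_image(image))
  stopf("expected an rgb_image or H x W x 3 array")
}

#' Segment olives from the support background
#'
#' Thresholds the blue channel (Otsu or fixed level), applies a morphological
#' closing, and discards connected components below the minimum olive area.
#'
#' @param image an [rgb_image()] or `H x W x 3` array.
#' @param cfg a [segmentation_config()].
#' @return Logical `H x W` matrix, `TRUE` on olive (foreground) pixels.
#' @export
segment_background <- function(image, cfg = segmentation_config()) {
  image <- as_rgb_image(image)
  blue <- channel_matrix(image, 3)
  red <- channel_matrix(image, 1)
  thr <- if (cfg$background_threshold_mode == "otsu") {
    255 * EBImage::otsu(EBImage::Image(t(blue) / 255), range = c(0, 1))
  } else {
    cfg$blue_fixed_threshold
  }
  mask <- if (cfg$background_colour == "dark") {
    blue > thr
  } else {
    # blue support: background is strongly blue with little red
    !(blue > thr & red < 100)
  }
  if (cfg$morphology_radius_px > 0) {
    size <- 2L * cfg$morphology_radius_px + 1L
    brush <- EBImage::makeBrush(size, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(t(mask) * 1), brush)
    mask <- t(EBImage::imageData(closed)) > 0.5
  }
  drop_small_components(mask, cfg$min_olive_area_px)
}

# remove connected components below min_area (8-connectivity via bwlabel)
drop_small_components <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1))))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow = nrow(mask))
}

#' Label olives and assign them to alveolar grid cells
#'
#' Connected foreground components are labelled and each is assigned to the
#' grid cell containing its centroid, with cells tiled uniformly over the
#' image extent. Indexing is 0-based row-major: row 0 at the top, column 0 at
#' the left. When two components land in one cell only the larger is kept;
#' components beyond the grid capacity are dropped by area rank with a
#' warning.
#'
#' @param mask logical foreground mask from [segment_background()].
#' @param layout a [grid_layout()].
#' @return `data.frame` with columns `label`, `grid_row`, `grid_col`,
#'   `area_px`, `centroid_row`, `centroid_col`, at most one row per cell.
#' @export
detect_olives <- function(mask, layout = grid_layout()) {
  if (!is.matrix(mask) || !is.logical(mask)) stopf("mask must be a logical matrix")
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) {
    return(data.frame(label = integer(), grid_row = integer(),
                      grid_col = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric()))
  }
  lab_img <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  lab <- t(EBImage::imageData(lab_img))
  n <- max(lab)
  area <- tabulate(lab[lab > 0], nbins = n)
  idx <- which(lab > 0, arr.ind = TRUE)
  centroid_row <- vapply(seq_len(n), function(k)
    mean(idx[lab[idx] == k, 1]), numeric(1))
  centroid_col <- vapply(seq_len(n), function(k)
    mean(idx[lab[idx] == k, 2]), numeric(1))
  grid_row <- pmin(floor((centroid_row - 0.5) / (h / layout$n_rows)),
                   layout$n_rows - 1L)
  grid_col <- pmin(floor((centroid_col - 0.5) / (w / layout$n_cols)),
                   layout$n_cols - 1L)
  out <- data.frame(label = seq_len(n), grid_row = as.integer(grid_row),
                    grid_col = as.integer(grid_col), area_px = area,
                    centroid_row = centroid_row, centroid_col = centroid_col)
  if (nrow(out) > layout$expected_count)
    warnf("%d components exceed grid capacity %d; dropping smallest",
          nrow(out), layout$expected_count)
  # largest-wins within each cell, then cap at grid capacity by area rank
  out <- out[order(-out$area_px), ]
  out <- out[!duplicated(out[, c("grid_row", "grid_col")]), ]
  out <- utils::head(out, layout$expected_count)
  out <- out[order(out$grid_row, out$grid_col), ]
  rownames(out) <- NULL
  out
}

#' Classify foreground pixels as NaOH-treated
#'
#' In `channel_difference` mode a foreground pixel is treated iff
#' `R - G >= red_minus_green_min` and `R >= red_min`; in `hue_band` mode iff
#' its hue falls in `hue_band_deg`. Treated pixels are always a subset of the
#' foreground.
#'
#' @param image an [rgb_image()] or array.
#' @param mask logical foreground mask.
#' @param cfg a [classifier_config()].
#' @return Logical `H x W` matrix of treated pixels.
#' @export
classify_treated <- function(image, mask, cfg = classifier_config()) {
  image <- as_rgb_image(image)
  if (!identical(dim(mask), dim(image$pixels)[1:2]))
    stopf("mask dimensions do not match image")
  r <- channel_matrix(image, 1)
  g <- channel_matrix(image, 2)
  b <- channel_matrix(image, 3)
  treated <- if (cfg$mode == "channel_difference") {
    (r - g >= cfg$red_minus_green_min) & (r >= cfg$red_min)
  } else {
    hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g),
                              b = as.vector(b), maxColorValue = 255)
    hue <- matrix(hsv[1, ] * 360, nrow = nrow(r))
    lo <- cfg$hue_band_deg[1]; hi <- cfg$hue_band_deg[2]
    if (lo <= hi) hue >= lo & hue <= hi else hue >= lo | hue <= hi
  }
  if (cfg$exclude_specular)
    treated <- treated & !(r >= 250 & g >= 250 & b >= 250)
  treated & mask
}

#' Measure the lye-treatment percentage of a grid image
#'
#' Full pipeline: segment the background, assign olives to alveolar cells,
#' classify treated pixels, and compute per-olive and whole-grid treated
#' percentages. `pooled_pct` is the area-pooled percentage
#' (`100 * sum(treated) / sum(total)`, the headline estimate of the surface
#' affected); `mean_pct` is the unweighted mean of per-olive percentages.
#'
#' @param image an [rgb_image()], array, or path to a JPEG/PNG file.
#' @param layout a [grid_layout()].
#' @param seg_cfg a [segmentation_config()].
#' @param cls_cfg a [classifier_config()].
#' @return Object of class `grid_measurement`: list with `olives`
#'   (data.frame: `grid_row`, `grid_col`, `total_area_px`, `treated_area_px`,
#'   `treated_pct`), `pooled_pct`, `mean_pct`, `n_detected`, `layout`.
#' @export
measure_grid <- function(image, layout = grid_layout(),
                         seg_cfg = segmentation_config(),
                         cls_cfg = classifier_config()) {
  if (is.character(image)) image <- read_olive_image(image)
  image <- as_rgb_image(image)
  mask <- segment_background(image, seg_cfg)
  olives <- detect_olives(mask, layout)
  if (nrow(olives) == 0L)
    stopf("no olives detected in image; check segmentation settings")
  # restrict mask to kept components so dropped debris is not measured
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1))))
  treated <- classify_treated(image, mask, cls_cfg)
  total_px <- integer(nrow(olives)); treated_px <- integer(nrow(olives))
  for (i in seq_len(nrow(olives))) {
    sel <- lab == olives$label[i]
    total_px[i] <- sum(sel)
    treated_px[i] <- sum(treated & sel)
  }
  df <- data.frame(grid_row = olives$grid_row, grid_col = olives$grid_col,
                   total_area_px = total_px, treated_area_px = treated_px,
                   treated_pct = 100 * treated_px / total_px)
  structure(list(olives = df,
                 pooled_pct = 100 * sum(treated_px) / sum(total_px),
                 mean_pct = mean(df$treated_pct),
                 n_detected = nrow(df),
                 layout = layout),
            class = "grid_measurement")
}

#' @export
print.grid_measurement <- function(x, ...) {
  cat(sprintf("<grid_measurement: %d olives, pooled %.1f%%, mean %.1f%%>\n",
              x$n_detected, x$pooled_pct, x$mean_pct))
  invisible(x)
}

#' Average replicate grid measurements
#'
#' Several scans of the same time point are averaged: the replicate-set
#' percentage is the arithmetic mean of the member pooled percentages.
#'
#' @param measurements non-empty list of `grid_measurement` objects.
#' @return Object of class `replicate_set` with fields `measurements`,
#'   `mean_pct`, `n`.
#' @export
average_replicates <- function(measurements) {
  if (length(measurements) == 0L) stopf("empty replicate list")
  ok <- vapply(measurements, inherits, logical(1), "grid_measurement")
  if (!all(ok)) stopf("all elements must be grid_measurement objects")
  pooled <- vapply(measurements, `[[`, numeric(1), "pooled_pct")
  structure(list(measurements = measurements, mean_pct = mean(pooled),
                 n = length(measurements)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set: %d scans, mean %.1f%%>\n", x$n, x$mean_pct))
  invisible(x)
}

#' Write per-olive measurements to CSV
#'
#' One row per detected olive: `sample_id`, `grid_row`, `grid_col`,
#' `total_area_px`, `treated_area_px`, `treated_pct`.
#'
#' @param measurement a `grid_measurement`.
#' @param path output CSV path.
#' @param sample_id identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(measurement, path, sample_id = "sample") {
  df <- measurement$olives
  df <- cbind(data.frame(sample_id = rep(sample_id, nrow(df))), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a grid summary to JSON
#'
#' @param measurement a `grid_measurement`.
#' @param path output JSON path.
#' @param sample_id identifier included in the summary.
#' @return `path`, invisibly.
#' @export
write_measurement_json <- function(measurement, path, sample_id = "sample") {
  jsonlite::write_json(list(sample_id = sample_id,
                            pooled_pct = measurement$pooled_pct,
                            mean_pct = measurement$mean_pct,
                            n_detected = measurement$n_detected),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
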