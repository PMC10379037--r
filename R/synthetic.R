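#' Specification of a synthetic olive-grid image
#'
#' Parameters for rendering a ground-truth grid image: elliptical olive halves
#' at the centres of a uniform alveolar tiling, each with an outer treated
#' annulus. The lye attacks the skin first and advances inward, so the
#' stained (fuchsia) region is modelled as a concentric annulus whose area
#' fraction equals the requested treated fraction; the untreated core keeps
#' the yellow-green flesh colour.
#'
#' @param layout a [grid_layout()].
#' @param image_size_px integer `c(width, height)` of the rendered image.
#' @param olive_axes_px numeric `c(a, b)`: ellipse semi-axes in pixels
#'   (a horizontal, b vertical) before per-olive jitter.
#' @param per_olive_treated_fraction treated-area fractions in `[0, 1]`, one
#'   per grid cell (row-major), or a single value recycled.
#' @param flesh_color,stain_color,background_color RGB triples in 0--255.
#'   Defaults: yellow-green flesh, fuchsia stain, near-black support.
#' @param noise_sigma standard deviation of additive Gaussian channel noise
#'   (0 disables noise).
#' @param axis_jitter relative jitter of the semi-axes per olive (uniform in
#'   `[1 - j, 1 + j]`), so olives differ in size as real fruit do.
#' @param seed RNG seed for jitter and noise (NULL: use current RNG state).
#' @return Object of class `synthetic_grid_spec`.
#' @export
synthetic_grid_spec <- function(layout = grid_layout(4, 6),
                                image_size_px = c(720, 480),
                                olive_axes_px = c(38, 42),
                                per_olive_treated_fraction = 0.4,
                                flesh_color = c(150, 160, 60),
                                stain_color = c(200, 60, 120),
                                background_color = c(5, 5, 5),
                                noise_sigma = 0,
                                axis_jitter = 0.08,
                                seed = 1L) {
  frac <- rep_len(per_olive_treated_fraction, layout$expected_count)
  if (any(frac < 0 | frac > 1)) stopf("treated fractions must lie in [0, 1]")
  for (col in list(flesh_color, stain_color, background_color))
    if (length(col) != 3L || any(col < 0 | col > 255))
      stopf("colors must be RGB triples in [0, 255]")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  cell_w <- image_size_px[1] / layout$n_cols
  cell_h <- image_size_px[2] / layout$n_rows
  if (olive_axes_px[1] * (1 + axis_jitter) >= 0.48 * cell_w ||
      olive_axes_px[2] * (1 + axis_jitter) >= 0.48 * cell_h)
    stopf("olives would overlap cell boundaries; shrink olive_axes_px")
  structure(list(layout = layout, image_size_px = as.integer(image_size_px),
                 olive_axes_px = olive_axes_px,
                 per_olive_treated_fraction = frac,
                 flesh_color = flesh_color, stain_color = stain_color,
                 background_color = background_color,
                 noise_sigma = noise_sigma, axis_jitter = axis_jitter,
                 seed = seed),
            class = "synthetic_grid_spec")
}

#' Render a synthetic olive-grid image with ground truth
#'
#' Draws one ellipse per alveolar cell. A treated fraction `f` is realised as
#' the outer annulus of normalised elliptical radius `sqrt(1 - f) < r <= 1`,
#' whose continuous area fraction is exactly `f`; pixel discretisation keeps
#' the rendered fraction within about 1% of the request for the default
#' olive sizes. Optional Gaussian channel noise is added after composition.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [synthetic_grid_spec()].
#' @return List of class `synthetic_grid`: `image` (an [rgb_image()]) and
#'   `truth` (data.frame: `grid_row`, `grid_col`, `fraction_requested`,
#'   `total_px`, `treated_px`, `fraction_rendered`).
#' @export
render_grid <- function(spec) {
  stopifnot(inherits(spec, "synthetic_grid_spec"))
  with_seed(spec$seed, {
    w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
    lay <- spec$layout
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) px[, , ch] <- spec$background_color[ch]
    cell_w <- w / lay$n_cols; cell_h <- h / lay$n_rows
    truth <- data.frame()
    k <- 0L
    for (r in seq_len(lay$n_rows) - 1L) {
      for (cc in seq_len(lay$n_cols) - 1L) {
        k <- k + 1L
        f <- spec$per_olive_treated_fraction[k]
        jit <- stats::runif(2, 1 - spec$axis_jitter, 1 + spec$axis_jitter)
        a <- spec$olive_axes_px[1] * jit[1]
        b <- spec$olive_axes_px[2] * jit[2]
        cx <- (cc + 0.5) * cell_w; cy <- (r + 0.5) * cell_h
        cols <- seq(max(1, floor(cx - a)), min(w, ceiling(cx + a)))
        rows <- seq(max(1, floor(cy - b)), min(h, ceiling(cy + b)))
        # pixel centres at integer coordinates - 0.5
        rho2 <- outer(((rows - 0.5 - cy) / b)^2, ((cols - 0.5 - cx) / a)^2, `+`)
        fg <- rho2 <= 1
        treated <- fg & rho2 > (1 - f)
        for (ch in 1:3) {
          block <- px[rows, cols, ch]
          block[fg] <- spec$flesh_color[ch]
          block[treated] <- spec$stain_color[ch]
          px[rows, cols, ch] <- block
        }
        truth <- rbind(truth, data.frame(
          grid_row = r, grid_col = cc, fraction_requested = f,
          total_px = sum(fg), treated_px = sum(treated),
          fraction_rendered = sum(treated) / sum(fg)))
      }
    }
    if (spec$noise_sigma > 0) {
      px <- px + stats::rnorm(length(px), 0, spec$noise_sigma)
      px <- clamp(px, 0, 255)
    }
    structure(list(image = rgb_image(px), truth = truth),
              class = "synthetic_grid")
  })
}

#' Write a rendered grid to PNG with its ground-truth CSV
#'
#' @param grid a `synthetic_grid` from [render_grid()].
#' @param png_path output PNG path.
#' @param truth_path optional CSV path for the ground-truth table.
#' @return `png_path`, invisibly.
#' @export
write_grid_png <- function(grid, png_path, truth_path = NULL) {
  stopifnot(inherits(grid, "synthetic_grid"))
  EBImage::writeImage(
    EBImage::Image(aperm(grid$image$pixels / 255, c(2, 1, 3)),
                   colormode = "Color"),
    png_path)
  if (!is.null(truth_path))
    utils::write.csv(grid$truth, truth_path, row.names = FALSE)
  invisible(png_path)
}

#' Specification of a synthetic cooking curve
#'
#' The lye-treatment percentage over time follows a sigmoid with a slow
#' initial phase (the skin resists penetration), a fast middle phase and a
#' saturating tail. A logistic is used:
#' `raw(t) = saturation_pct / (1 + exp(-rate * (t' - midpoint_h)))` with
#' `t' = max(t - lag_h, 0)`, shifted so the curve starts at 0% and clipped to
#' `[0, 100]`.
#'
#' @param lag_h dead time before penetration starts (hours).
#' @param rate logistic growth rate (per hour).
#' @param midpoint_h time of the logistic midpoint (hours, after the lag).
#' @param saturation_pct asymptotic percentage in `(0, 100]`; 84.3 by
#'   default, a typical expert end-point percentage.
#' @param sample_interval_h sampling cadence (hours).
#' @param duration_h total observed duration (hours).
#' @param noise_sigma_pct standard deviation of observation noise
#'   (percentage points); observations are clipped to `[0, 100]`.
#' @param seed RNG seed for the noise (NULL: current RNG state).
#' @return Object of class `synthetic_curve_spec`.
#' @export
synthetic_curve_spec <- function(lag_h = 0, rate = 1.1, midpoint_h = 4.5,
                                 saturation_pct = 84.3,
                                 sample_interval_h = 1, duration_h = 8,
                                 noise_sigma_pct = 1, seed = 1L) {
  if (duration_h <= 0 || sample_interval_h <= 0)
    stopf("duration_h and sample_interval_h must be positive")
  if (saturation_pct <= 0 || saturation_pct > 100)
    stopf("saturation_pct must lie in (0, 100]")
  if (noise_sigma_pct < 0) stopf("noise_sigma_pct must be >= 0")
  structure(list(lag_h = lag_h, rate = rate, midpoint_h = midpoint_h,
                 saturation_pct = saturation_pct,
                 sample_interval_h = sample_interval_h,
                 duration_h = duration_h, noise_sigma_pct = noise_sigma_pct,
                 seed = seed),
            class = "synthetic_curve_spec")
}

#' Noise-free synthetic cooking percentage
#'
#' Evaluates the logistic of a [synthetic_curve_spec()] without noise: the
#' ground-truth curve underlying [sample_curve()].
#'
#' @param t times in hours.
#' @param spec a [synthetic_curve_spec()].
#' @return Percentages in `[0, 100]`.
#' @export
logistic_pct <- function(t, spec) {
  te <- pmax(t - spec$lag_h, 0)
  raw <- function(u) spec$saturation_pct / (1 + exp(-spec$rate * (u - spec$midpoint_h)))
  clamp(raw(te) - raw(0), 0, 100)
}

#' Time at which the noise-free synthetic curve reaches a target
#'
#' @param spec a [synthetic_curve_spec()].
#' @param target_pct target percentage; must be below the curve's effective
#'   asymptote.
#' @param t_max upper search bound (hours).
#' @return Crossing time in hours.
#' @export
true_crossing_time <- function(spec, target_pct, t_max = 48) {
  if (logistic_pct(t_max, spec) < target_pct)
    stopf("curve never reaches %.1f%% within %g h", target_pct, t_max)
  stats::uniroot(function(t) logistic_pct(t, spec) - target_pct,
                 lower = 0, upper = t_max, tol = 1e-9)$root
}

#' Sample a synthetic cooking curve
#'
#' Evaluates the logistic at `sample_interval_h, 2*sample_interval_h, ...`
#' up to `duration_h`, adds Gaussian observation noise and clips to
#' `[0, 100]`. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [synthetic_curve_spec()].
#' @param t_end_h anchor end time of the returned [cooking_curve()].
#' @return A `cooking_curve` whose `spec` attribute carries the generating
#'   parameters.
#' @export
sample_curve <- function(spec, t_end_h = 24) {
  stopifnot(inherits(spec, "synthetic_curve_spec"))
  times <- seq(spec$sample_interval_h, spec$duration_h,
               by = spec$sample_interval_h)
  pct <- logistic_pct(times, spec)
  with_seed(spec$seed, {
    if (spec$noise_sigma_pct > 0)
      pct <- clamp(pct + stats::rnorm(length(pct), 0, spec$noise_sigma_pct),
                   0, 100)
    curve <- cooking_curve(times, pct, t_end_h = t_end_h)
    attr(curve, "spec") <- spec
    curve
  })
}
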