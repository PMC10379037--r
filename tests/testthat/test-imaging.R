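test_that("segment_background finds nothing in an all-dark image", {
  img <- rgb_image(array(0, dim = c(40, 60, 3)))
  mask <- segment_background(img, segmentation_config("fixed",
                                                      blue_fixed_threshold = 40))
  expect_false(any(mask))
})

test_that("segmentation recovers the rendered component count", {
  g <- render_grid(small_grid_spec(2, 3, frac = 0.5))
  mask <- segment_background(g$image)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1))))
  expect_equal(max(lab), 6)
})

test_that("the minimum-area filter removes small components", {
  px <- array(0, dim = c(100, 100, 3))
  px[40:60, 40:60, ] <- 150            # 441 px square
  img <- rgb_image(px)
  cfg_keep <- segmentation_config("fixed", blue_fixed_threshold = 40,
                                  min_olive_area_px = 100,
                                  morphology_radius_px = 0)
  cfg_drop <- segmentation_config("fixed", blue_fixed_threshold = 40,
                                  min_olive_area_px = 1000,
                                  morphology_radius_px = 0)
  expect_equal(sum(segment_background(img, cfg_keep)), 441)
  expect_false(any(segment_background(img, cfg_drop)))
})

test_that("detect_olives assigns components to the rendered grid cells", {
  g <- render_grid(small_grid_spec(2, 3, frac = 0.3))
  det <- detect_olives(segment_background(g$image), grid_layout(2, 3))
  expect_equal(nrow(det), 6)
  expect_equal(det[, c("grid_row", "grid_col")],
               g$truth[, c("grid_row", "grid_col")],
               ignore_attr = TRUE)
  # empty mask: empty assignment
  empty <- detect_olives(matrix(FALSE, 10, 10), grid_layout(2, 3))
  expect_equal(nrow(empty), 0)
})

test_that("two components in one cell: the larger wins", {
  px <- array(0, dim = c(80, 80, 3))
  px[10:40, 10:40, ] <- 150   # 961 px, centroid in cell (0, 0) of 1x1 grid
  px[60:70, 60:70, ] <- 150   # 121 px, same single cell
  mask <- segment_background(rgb_image(px),
                             segmentation_config("fixed", 40,
                                                 min_olive_area_px = 50,
                                                 morphology_radius_px = 0))
  expect_warning(det <- detect_olives(mask, grid_layout(1, 1)),
                 "grid capacity")
  expect_equal(nrow(det), 1)
  expect_equal(det$area_px, 961)
})

test_that("extra components beyond grid capacity are dropped with a warning", {
  px <- array(0, dim = c(60, 180, 3))
  for (k in 0:2) px[20:40, (20:40) + 60 * k, ] <- 150
  mask <- segment_background(rgb_image(px),
                             segmentation_config("fixed", 40,
                                                 min_olive_area_px = 50,
                                                 morphology_radius_px = 0))
  expect_warning(det <- detect_olives(mask, grid_layout(1, 2)),
                 "grid capacity")
  expect_equal(nrow(det), 2)
})

test_that("classify_treated implements the channel-difference rule", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- c(200, 60, 120)   # fuchsia: 200 - 60 = 140 >= 40, R >= 100
  px[1, 2, ] <- c(150, 160, 60)   # yellow-green: 150 - 160 = -10 < 40
  px[1, 3, ] <- c(0, 0, 0)        # background
  img <- rgb_image(px)
  mask <- matrix(c(TRUE, TRUE, FALSE), nrow = 1)
  treated <- classify_treated(img, mask,
                              classifier_config(red_minus_green_min = 40,
                                                red_min = 100))
  expect_equal(as.vector(treated), c(TRUE, FALSE, FALSE))
  # background pixel never treated even with a permissive config
  permissive <- classifier_config(red_minus_green_min = -255, red_min = 0)
  expect_false(any(classify_treated(img, matrix(FALSE, 1, 3), permissive)))
  # specular highlight excluded
  px[1, 2, ] <- c(255, 255, 255)
  spec_mask <- classify_treated(rgb_image(px), matrix(TRUE, 1, 3),
                                classifier_config(red_minus_green_min = -255,
                                                  red_min = 0))
  expect_false(spec_mask[1, 2])
})

test_that("hue-band mode selects fuchsia and handles wraparound", {
  px <- array(0, dim = c(1, 2, 3))
  px[1, 1, ] <- c(200, 60, 120)   # hue ~ 334 deg
  px[1, 2, ] <- c(150, 160, 60)   # hue ~ 66 deg
  img <- rgb_image(px)
  mask <- matrix(TRUE, 1, 2)
  treated <- classify_treated(img, mask,
                              classifier_config("hue_band",
                                                hue_band_deg = c(300, 30)))
  expect_equal(as.vector(treated), c(TRUE, FALSE))
})

test_that("measure_grid recovers rendered fractions and conserves areas", {
  g <- render_grid(small_grid_spec(2, 3, frac = c(0, .2, .4, .6, .8, 1)))
  m <- measure_grid(g$image, grid_layout(2, 3))
  expect_equal(m$n_detected, 6)
  truth_pooled <- 100 * sum(g$truth$treated_px) / sum(g$truth$total_px)
  expect_lt(abs(m$pooled_pct - truth_pooled), 1)
  # conservation and range invariants
  expect_true(all(m$olives$treated_area_px <= m$olives$total_area_px))
  expect_true(all(m$olives$treated_pct >= 0 & m$olives$treated_pct <= 100))
  expect_gte(m$pooled_pct, min(m$olives$treated_pct))
  expect_lte(m$pooled_pct, max(m$olives$treated_pct))
  expect_equal(m$olives$treated_pct,
               100 * m$olives$treated_area_px / m$olives$total_area_px)
  # fully stained and unstained extremes
  m0 <- measure_grid(render_grid(small_grid_spec(2, 3, 0))$image,
                     grid_layout(2, 3))
  expect_lt(m0$pooled_pct, 1)
  m1 <- measure_grid(render_grid(small_grid_spec(2, 3, 1))$image,
                     grid_layout(2, 3))
  expect_gt(m1$pooled_pct, 99)
})

test_that("measure_grid raises an explicit error when no olives are present", {
  img <- rgb_image(array(0, dim = c(60, 60, 3)))
  expect_error(measure_grid(img, grid_layout(2, 3),
                            segmentation_config("fixed", 40)),
               "no olives")
})

test_that("pooled percentage is invariant to olive permutation and monotone in staining", {
  base <- c(0.1, 0.3, 0.5, 0.6, 0.8, 0.9)
  # identical olives (no size jitter) so only the positions change
  m_a <- measure_grid(render_grid(small_grid_spec(2, 3, base,
                                                  jitter = 0))$image,
                      grid_layout(2, 3))
  m_b <- measure_grid(render_grid(small_grid_spec(2, 3, rev(base),
                                                  jitter = 0))$image,
                      grid_layout(2, 3))
  expect_lt(abs(m_a$pooled_pct - m_b$pooled_pct), 0.1)
  # raising one olive's fraction never decreases the pooled percentage
  bumped <- base; bumped[2] <- 0.9
  m_c <- measure_grid(render_grid(small_grid_spec(2, 3, bumped,
                                                  jitter = 0))$image,
                      grid_layout(2, 3))
  expect_gte(m_c$pooled_pct, m_a$pooled_pct)
})

test_that("replicate averaging is the mean of pooled percentages", {
  ms <- lapply(c(1, 2, 3), function(s)
    measure_grid(render_grid(small_grid_spec(2, 3, 0.4, seed = s))$image,
                 grid_layout(2, 3)))
  rs <- average_replicates(ms)
  expect_equal(rs$mean_pct, mean(vapply(ms, `[[`, 1, "pooled_pct")))
  expect_equal(average_replicates(ms[1])$mean_pct, ms[[1]]$pooled_pct)
  expect_error(average_replicates(list()), "empty")
})

test_that("PNG round trip preserves the measurement", {
  g <- render_grid(small_grid_spec(2, 3, 0.5))
  path <- withr::local_tempfile(fileext = ".png")
  write_grid_png(g, path)
  m_disk <- measure_grid(path, grid_layout(2, 3))
  m_mem <- measure_grid(g$image, grid_layout(2, 3))
  expect_equal(m_disk$pooled_pct, m_mem$pooled_pct, tolerance = 0.2)
  expect_equal(m_disk$n_detected, 6)
})

test_that("measurement outputs serialise to CSV and JSON", {
  m <- measure_grid(render_grid(small_grid_spec(2, 3, 0.4))$image,
                    grid_layout(2, 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_measurement_csv(m, csv, sample_id = "s1")
  write_measurement_json(m, js, sample_id = "s1")
  df <- read.csv(csv)
  expect_named(df, c("sample_id", "grid_row", "grid_col", "total_area_px",
                     "treated_area_px", "treated_pct"))
  expect_equal(nrow(df), 6)
  j <- jsonlite::read_json(js)
  expect_equal(j$n_detected, 6)
  expect_equal(j$pooled_pct, m$pooled_pct, tolerance = 1e-9)
})
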