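# shared fixtures: small fast synthetic specs for unit tests

small_grid_spec <- function(n_rows = 2, n_cols = 3, frac = 0.4, noise = 0,
                            seed = 1L, jitter = 0.08) {
  synthetic_grid_spec(layout = grid_layout(n_rows, n_cols),
                      image_size_px = c(n_cols * 80L, n_rows * 80L),
                      olive_axes_px = c(26, 30),
                      per_olive_treated_fraction = frac,
                      noise_sigma = noise, seed = seed,
                      axis_jitter = jitter)
}

# a deterministic monotone curve with known linear segments
stair_curve <- function() cooking_curve(c(1, 2, 3), c(10, 30, 70), t_end_h = 24)

# random strictly monotone cooking curve for property tests
random_monotone_curve <- function(n_obs = 6, t_end_h = 24) {
  t <- sort(runif(n_obs, 0.5, t_end_h - 1))
  while (any(diff(t) < 1e-3)) t <- sort(runif(n_obs, 0.5, t_end_h - 1))
  p <- cumsum(runif(n_obs, 1, 15))
  p <- 95 * p / max(p) * runif(1, 0.6, 1)
  cooking_curve(t, p, t_end_h = t_end_h)
}

# brute-force first-crossing oracle on a dense grid
brute_force_crossing <- function(f, t_end, target, step) {
  grid <- seq(0, t_end, by = step)
  vals <- f(grid)
  grid[which(vals >= target)[1]]
}
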