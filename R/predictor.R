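#' Cooking curve of a lye-treatment tank
#'
#' Ordered observations of the lye-treatment percentage over time for one
#' tank, together with the anchor policy: the process starts at `(0 h, 0%)`
#' and, if left far past its optimal point, ends fully treated at
#' `(t_end_h, 100%)` (24 h by default, the maximum recommended duration).
#' These two anchors are appended as ordinary knots before any interpolant is
#' fitted, dynamically correcting predictions made from few samples.
#'
#' @param time_h observation times in hours since NaOH addition; strictly
#'   increasing, all in `(0, t_end_h)`.
#' @param pct lye-treatment percentages in `[0, 100]`.
#' @param t_end_h time of the 100% anchor (hours).
#' @return Object of class `cooking_curve` with fields `observations`
#'   (data.frame `time_h`, `pct`), `t_end_h`.
#' @export
cooking_curve <- function(time_h = numeric(), pct = numeric(), t_end_h = 24) {
  if (length(time_h) != length(pct)) stopf("time_h and pct lengths differ")
  if (!is_num1(t_end_h) || t_end_h <= 0) stopf("t_end_h must be positive")
  if (length(time_h)) {
    if (anyNA(time_h) || anyNA(pct)) stopf("observations contain NA")
    if (any(diff(time_h) <= 0)) stopf("observation times must be strictly increasing")
    if (any(time_h <= 0 | time_h >= t_end_h))
      stopf("observation times must lie strictly between 0 and t_end_h = %g", t_end_h)
    if (any(pct < 0 | pct > 100)) stopf("percentages must lie in [0, 100]")
  }
  structure(list(observations = data.frame(time_h = as.numeric(time_h),
                                           pct = as.numeric(pct)),
                 t_end_h = t_end_h),
            class = "cooking_curve")
}

#' @export
print.cooking_curve <- function(x, ...) {
  cat(sprintf("<cooking_curve: %d observations, anchors (0, 0%%) and (%g h, 100%%)>\n",
              nrow(x$observations), x$t_end_h))
  if (nrow(x$observations)) print(x$observations)
  invisible(x)
}

#' Read a cooking curve from CSV
#'
#' Expects a header `time_h,pct` with one cook per file.
#'
#' @param path CSV path.
#' @param t_end_h anchor end time passed to [cooking_curve()].
#' @return A `cooking_curve`.
#' @export
read_cooking_curve <- function(path, t_end_h = 24) {
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stopf("cannot parse curve CSV %s: %s", path, conditionMessage(e)))
  if (!all(c("time_h", "pct") %in% names(df)))
    stopf("curve CSV %s must have columns time_h,pct", path)
  time_h <- suppressWarnings(as.numeric(df$time_h))
  pct <- suppressWarnings(as.numeric(df$pct))
  bad <- which(!is.finite(time_h) | !is.finite(pct))
  if (length(bad))
    stopf("malformed value in %s at data line %d", path, bad[1])
  df <- data.frame(time_h = time_h, pct = pct)
  cooking_curve(df$time_h, df$pct, t_end_h = t_end_h)
}

# anchored knot set: (0, 0), first n observations, (t_end, 100)
curve_knots <- function(curve, n_samples = NULL) {
  obs <- curve$observations
  if (!is.null(n_samples)) {
    if (n_samples > nrow(obs)) stopf("n_samples exceeds available observations")
    obs <- obs[seq_len(n_samples), , drop = FALSE]
  }
  x <- c(0, obs$time_h, curve$t_end_h)
  y <- c(0, obs$pct, 100)
  if (anyDuplicated(x)) stopf("duplicate knot times after anchoring")
  list(x = x, y = y)
}

#' Fit an anchored interpolant to a cooking curve
#'
#' Appends the dynamic anchors `(0, 0)` and `(t_end_h, 100)` to the (possibly
#' truncated) observation list and fits the requested interpolant:
#' `"linear"` (piecewise linear), `"pchip"` (Fritsch--Carlson shape-preserving
#' cubic Hermite, monotone for monotone data) or `"makima"` (modified Akima
#' cubic Hermite; reduced overshoot but not guaranteed monotone). With fewer
#' than three knots the cubic methods reduce to the linear interpolant.
#'
#' @param curve a [cooking_curve()].
#' @param method `"linear"`, `"pchip"` or `"makima"`.
#' @param n_samples use only the first `n_samples` observations (default all).
#' @return A vectorised function `pct(t)` defined on `[0, t_end_h]`, passing
#'   through every knot exactly.
#' @export
build_interpolant <- function(curve, method = c("linear", "pchip", "makima"),
                              n_samples = NULL) {
  method <- match.arg(method)
  k <- curve_knots(curve, n_samples)
  if (method == "linear" || length(k$x) < 3L)
    return(stats::approxfun(k$x, k$y, rule = 2))
  if (method == "pchip") {
    function(t) pracma::pchip(k$x, k$y, clamp(t, k$x[1], k$x[length(k$x)]))
  } else {
    s <- makima_slopes(k$x, k$y)
    function(t) hermite_eval(k$x, k$y, s, t)
  }
}

#' Prediction settings
#'
#' @param method interpolation method (see [build_interpolant()]).
#' @param target_pct lye-treatment percentage at which the cook should stop.
#'   Default 66.7: the classical rule stops the lye when it has penetrated
#'   about two-thirds of the flesh.
#' @param grid_step_h resolution of the inverse-lookup scan grid (hours).
#' @param min_samples minimum number of observations required before a
#'   prediction is attempted.
#' @return Object of class `prediction_config`.
#' @export
prediction_config <- function(method = c("pchip", "linear", "makima"),
                              target_pct = 66.7, grid_step_h = 0.01,
                              min_samples = 4L) {
  method <- match.arg(method)
  if (!is_num1(target_pct) || target_pct <= 0 || target_pct > 100)
    stopf("target_pct must lie in (0, 100]")
  if (!is_num1(grid_step_h) || grid_step_h <= 0) stopf("grid_step_h must be > 0")
  if (!is_count(min_samples) || min_samples < 2) stopf("min_samples must be >= 2")
  structure(list(method = method, target_pct = target_pct,
                 grid_step_h = grid_step_h, min_samples = as.integer(min_samples)),
            class = "prediction_config")
}

# first t in [0, t_end] with f(t) >= target: coarse scan then bisection
first_crossing <- function(f, t_end, target, step, tol = 1e-6) {
  grid <- seq(0, t_end, by = step)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  vals <- f(grid)
  hit <- which(vals >= target)
  if (!length(hit)) return(NA_real_)  # cannot happen with the 100% anchor
  i <- hit[1]
  if (i == 1L) return(grid[1])
  lo <- grid[i - 1]; hi <- grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Predict the lye-treatment completion time
#'
#' Inverts the anchored interpolant: returns the earliest time at which the
#' interpolated percentage reaches `target_pct`, found by scanning a uniform
#' grid of step `grid_step_h` and refining the bracketing interval by
#' bisection to 1e-6 h. When a non-monotone (makima) interpolant crosses the
#' target more than once, the first crossing is returned — the earliest safe
#' stop time. The 100% anchor guarantees a crossing for any target <= 100.
#'
#' @param curve a [cooking_curve()].
#' @param config a [prediction_config()].
#' @param n_samples use only the first `n_samples` observations (default all).
#' @return Object of class `prediction_result`: `t_est_h`, `method`,
#'   `n_samples_used`, `target_pct`.
#' @export
predict_completion <- function(curve, config = prediction_config(),
                               n_samples = NULL) {
  n_obs <- if (is.null(n_samples)) nrow(curve$observations) else n_samples
  # anchors-only query (no observations at all) is a legitimate degenerate
  # case: the anchors themselves are knowledge. The guard applies once
  # sampling has started.
  if (n_obs > 0 && n_obs < config$min_samples)
    stopf("insufficient samples: %d observed, %d required",
          n_obs, config$min_samples)
  f <- build_interpolant(curve, config$method, n_samples)
  t_est <- first_crossing(f, curve$t_end_h, config$target_pct,
                          config$grid_step_h)
  structure(list(t_est_h = t_est, method = config$method,
                 n_samples_used = as.integer(n_obs),
                 target_pct = config$target_pct),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction: %s reaches %.1f%% at t = %.2f h (n = %d samples)>\n",
              x$method, x$target_pct, x$t_est_h, x$n_samples_used))
  invisible(x)
}

#' Signed relative completion-time error
#'
#' `100 * (t_est_h - t_real_h) / t_real_h`: positive for overestimates,
#' negative for underestimates (which err on the side of safety, alerting the
#' operator early).
#'
#' @param t_est_h estimated completion time (hours).
#' @param t_real_h real end time decided by the expert (hours, > 0).
#' @return Signed relative error in percent.
#' @export
relative_error <- function(t_est_h, t_real_h) {
  if (any(t_real_h <= 0)) stopf("t_real_h must be positive")
  100 * (t_est_h - t_real_h) / t_real_h
}

#' Prediction-error table over growing sample counts
#'
#' For each prefix of `n = min_samples, ..., N` observations (plus the two
#' anchors), predicts the completion time with each method and tabulates the
#' signed relative error against the real end time — the evolution of the
#' estimate as sampling proceeds.
#'
#' @param curve a [cooking_curve()].
#' @param config a [prediction_config()] (its `method` is ignored; all
#'   requested methods are tabulated).
#' @param t_real_h real end time (hours, > 0).
#' @param methods methods to tabulate.
#' @param digits round estimated times to this many decimals before forming
#'   errors, so the table arithmetic can be reproduced from its own printed
#'   values; `NULL` keeps full precision.
#' @return `data.frame` with columns `n_samples`, `t_<method>`..., `t_real`,
#'   `e_<method>`...
#' @export
running_prediction_table <- function(curve, config = prediction_config(),
                                     t_real_h,
                                     methods = c("linear", "pchip", "makima"),
                                     digits = 2) {
  if (!is_num1(t_real_h) || t_real_h <= 0) stopf("t_real_h must be positive")
  n_obs <- nrow(curve$observations)
  if (n_obs < config$min_samples)
    stopf("insufficient samples: %d observed, %d required", n_obs,
          config$min_samples)
  ns <- seq(config$min_samples, n_obs)
  out <- data.frame(n_samples = ns)
  for (m in methods) {
    cfg_m <- config; cfg_m$method <- m
    t_est <- vapply(ns, function(n)
      predict_completion(curve, cfg_m, n_samples = n)$t_est_h, numeric(1))
    if (!is.null(digits)) t_est <- round(t_est, digits)
    out[[paste0("t_", m)]] <- t_est
  }
  out$t_real <- t_real_h
  for (m in methods)
    out[[paste0("e_", m)]] <- relative_error(out[[paste0("t_", m)]], t_real_h)
  out
}

#' Mean absolute relative error
#'
#' Arithmetic mean of the absolute values of signed relative errors, the
#' aggregate benchmark used to compare interpolation methods across trials.
#'
#' @param errors non-empty numeric vector of signed percent errors.
#' @return Mean absolute error in percent.
#' @export
average_absolute_error <- function(errors) {
  if (!length(errors)) stopf("empty error list")
  if (anyNA(errors)) stopf("errors contain NA")
  mean(abs(errors))
}
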