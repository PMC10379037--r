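# Modified Akima (makima) piecewise cubic Hermite interpolation.
#
# Node slopes are weighted averages of neighbouring secant slopes d[i]:
#   w1 = |d[i+1] - d[i]|   + |d[i+1] + d[i]|   / 2
#   w2 = |d[i-1] - d[i-2]| + |d[i-1] + d[i-2]| / 2
#   s[i] = (w1 * d[i-1] + w2 * d[i]) / (w1 + w2)
# with the standard two-virtual-point linear extension of the secant sequence
# at each end. The |.+.|/2 terms (the modification over classic Akima) damp
# overshoot near flat regions; when w1 + w2 = 0 the slope falls back to the
# mean of the adjacent secants.

makima_slopes <- function(x, y) {
  n <- length(x)
  if (n < 2L) stopf("makima needs at least 2 knots")
  d <- diff(y) / diff(x)
  m <- length(d)
  if (m == 1L) {
    ext <- rep(d, 5)
  } else {
    dl1 <- 2 * d[1] - d[2];     dl2 <- 2 * dl1 - d[1]
    dr1 <- 2 * d[m] - d[m - 1]; dr2 <- 2 * dr1 - d[m]
    ext <- c(dl2, dl1, d, dr1, dr2)   # ext[j] = secant delta_{j-3+1}
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    # node i lies between ext[i+1] (left secant) and ext[i+2] (right secant)
    w1 <- abs(ext[i + 3] - ext[i + 2]) + abs(ext[i + 3] + ext[i + 2]) / 2
    w2 <- abs(ext[i + 1] - ext[i]) + abs(ext[i + 1] + ext[i]) / 2
    s[i] <- if (w1 + w2 == 0) {
      (ext[i + 1] + ext[i + 2]) / 2
    } else {
      (w1 * ext[i + 1] + w2 * ext[i + 2]) / (w1 + w2)
    }
  }
  s
}

# Evaluate a cubic Hermite interpolant with node slopes s at points t.
# Outside [x[1], x[n]] the boundary cubic is extended.
hermite_eval <- function(x, y, s, t) {
  n <- length(x)
  i <- findInterval(t, x, all.inside = TRUE)
  h <- x[i + 1] - x[i]
  u <- (t - x[i]) / h
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  h00 * y[i] + h10 * h * s[i] + h01 * y[i + 1] + h11 * h * s[i + 1]
}

#' Modified Akima (makima) interpolation
#'
#' Piecewise cubic Hermite interpolation with modified-Akima node slopes:
#' secant-slope differences are weighted so that flat regions do not ring,
#' while (unlike PCHIP) monotonicity of the data is not guaranteed.
#'
#' @param x strictly increasing knot abscissae (length >= 2).
#' @param y knot ordinates.
#' @param t evaluation points.
#' @return Interpolated values at `t`.
#' @seealso [build_interpolant()] for the anchored cooking-curve interface.
#' @export
makima <- function(x, y, t) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (any(diff(x) <= 0)) stopf("x must be strictly increasing")
  hermite_eval(x, y, makima_slopes(x, y), t)
}
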