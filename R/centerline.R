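#' Vessel centerline paths
#'
#' A `centerline` is an ordered chain of (possibly subpixel) points along one
#' branch-free vessel segment, with cumulative arc length (px) and unit tangent
#' vectors. It is the sampling path for kymographs and the anchor for diameter
#' normals. Points are 0-based `(y, x)`.
#'
#' Tangents come from central differences on a lightly smoothed copy of the
#' points (moving average, window 5) so that normals are stable against the
#' single-pixel staircase of a traced skeleton; the points themselves are kept
#' unsmoothed.
#'
#' @param points n x 2 matrix of (y, x) coordinates, n >= 2.
#' @param smooth_window odd window (in points) for tangent smoothing; 1 = none.
#' @return object of class `centerline` with fields `points`, `arc`
#'   (cumulative arc length, starts at 0, strictly increasing), `tangents`
#'   (n x 2, unit norm).
#' @export
centerline <- function(points, smooth_window = 5L) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop_mf("centerline needs an n x 2 matrix with n >= 2")
  step <- sqrt(rowSums(diff(points)^2))
  if (any(step == 0)) stop_mf("centerline has repeated consecutive points")
  arc <- c(0, cumsum(step))
  sm <- smooth_points(points, smooth_window)
  tg <- central_diff(sm)
  nrm <- sqrt(rowSums(tg^2))
  tg <- tg / nrm
  structure(list(points = points, arc = arc, tangents = tg),
            class = "centerline")
}

smooth_points <- function(p, window) {
  window <- as.integer(window)
  if (window <= 1L || nrow(p) < window) return(p)
  k <- rep(1 / window, window)
  pad <- (window - 1L) %/% 2L
  # pad by linear extrapolation so straight segments (and their endpoints)
  # are fixed points of the smoother
  smooth1 <- function(v) {
    n <- length(v)
    left <- v[1] - (pad:1) * (v[2] - v[1])
    right <- v[n] + (1:pad) * (v[n] - v[n - 1])
    v2 <- c(left, v, right)
    as.numeric(stats::filter(v2, k, sides = 2)[(pad + 1L):(pad + n)])
  }
  cbind(smooth1(p[, 1]), smooth1(p[, 2]))
}

central_diff <- function(p) {
  n <- nrow(p)
  if (n == 2L) return(rbind(p[2, ] - p[1, ], p[2, ] - p[1, ]))
  rbind(p[2, ] - p[1, ],
        (p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) / 2,
        p[n, ] - p[n - 1, ])
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, arc length %.1f px\n",
              nrow(x$points), max(x$arc)))
  invisible(x)
}

#' @export
length.centerline <- function(x) nrow(x$points)

#' Total arc length of a centerline, in pixels
#' @param path a `centerline`.
#' @return scalar arc length.
#' @export
arc_length <- function(path) max(path$arc)

#' Resample a centerline at equal arc-length spacing
#'
#' Linear interpolation along the chain; used to put kymograph columns at
#' exactly 1 px arc spacing and diameter normals at regular intervals.
#'
#' @param path a `centerline`.
#' @param spacing arc-length spacing in px (> 0).
#' @param s_range optional `c(s0, s1)` arc interval to resample (default whole
#'   path).
#' @return a new `centerline` whose points sit at `s0, s0+spacing, ...`.
#' @export
resample_centerline <- function(path, spacing = 1, s_range = NULL) {
  s_range <- s_range %||% c(0, max(path$arc))
  if (s_range[1] < 0 || s_range[2] > max(path$arc) + 1e-9 ||
      s_range[2] <= s_range[1])
    stop_mf("s_range [%g, %g] outside path arc [0, %g]",
            s_range[1], s_range[2], max(path$arc))
  s <- seq(s_range[1], s_range[2], by = spacing)
  y <- stats::approx(path$arc, path$points[, 1], xout = s)$y
  x <- stats::approx(path$arc, path$points[, 2], xout = s)$y
  centerline(cbind(y, x), smooth_window = 5L)
}

# interpolate (y, x) at arc positions s on a centerline
point_at_arc <- function(path, s) {
  cbind(stats::approx(path$arc, path$points[, 1], xout = s)$y,
        stats::approx(path$arc, path$points[, 2], xout = s)$y)
}
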