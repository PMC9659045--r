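#' Vessel diameter by FWHM of transverse intensity profiles
#'
#' Vessels absorb green light, so the green-channel intensity along a line
#' normal to the centerline dips inside the vessel. The diameter is read off
#' that dip as a full width at half maximum: the reference "maximum" is the
#' midpoint of the highest shoulder peak on each side of the dip, the level is
#' halfway between the dip minimum and that midpoint, and the width is the
#' distance between the subpixel crossings of that level on either side of
#' the minimum. Vessels are classified at the 20 um boundary: below it
#' capillaries, from 20 to 100 um arterioles/veins (the class whose velocity
#' is estimated), above 100 um out of range.
#'
#' @name diameter
NULL

#' Normals at regular arc-length intervals along a centerline
#'
#' @param path a [centerline()].
#' @param interval_px arc-length spacing of the normals (>= 1).
#' @return list of `list(point = c(y, x), normal = c(ny, nx))` with unit
#'   normals (tangent rotated by 90 degrees).
#' @export
compute_normals <- function(path, interval_px = 10) {
  stopifnot(inherits(path, "centerline"))
  assert_scalar_num(interval_px, "interval_px", 1)
  L <- arc_length(path)
  if (L < interval_px) stop_mf("path (%.1f px) shorter than interval", L)
  s <- seq(0, L, by = interval_px)
  s <- s[s < L - 1e-9]          # normals sit strictly inside the path
  pts <- point_at_arc(path, s)
  ty <- stats::approx(path$arc, path$tangents[, 1], xout = s)$y
  tx <- stats::approx(path$arc, path$tangents[, 2], xout = s)$y
  lapply(seq_along(s), function(i) {
    tg <- c(ty[i], tx[i]) / sqrt(ty[i]^2 + tx[i]^2)
    list(point = pts[i, ], normal = c(tg[2], -tg[1]))
  })
}

#' Sample a transverse intensity profile
#'
#' Bilinear samples at unit spacing along the normal, centered on the
#' centerline point: `2 * half_length_px + 1` values. The normal is
#' normalized internally if not unit length.
#'
#' @param green_frame H x W matrix.
#' @param point `c(y, x)` centerline point (0-based, subpixel).
#' @param normal `c(ny, nx)` direction.
#' @param half_length_px samples on each side (pick ~ 2.5x the expected
#'   maximum vessel radius).
#' @return `transverse_profile`: `positions` (offsets in px), `values`,
#'   `center_index` (1-based index of offset 0).
#' @export
sample_profile <- function(green_frame, point, normal, half_length_px = 40) {
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop_mf("normal must be non-zero")
  normal <- normal / nn
  off <- (-half_length_px):half_length_px
  ys <- point[1] + off * normal[1]
  xs <- point[2] + off * normal[2]
  h <- nrow(green_frame); w <- ncol(green_frame)
  if (any(ys < 0 | ys > h - 1 | xs < 0 | xs > w - 1))
    stop_mf("profile exits frame")
  structure(list(positions = off,
                 values = bilinear_sample(green_frame, ys, xs),
                 center_index = half_length_px + 1L),
            class = "transverse_profile")
}

#' FWHM diameter from a transverse profile
#'
#' Implements the shoulder-midpoint FWHM rule. Extremum *locations* are found
#' on a lightly smoothed copy (moving average, width 3) so single-pixel noise
#' does not dictate the peaks; the level and the crossings use the raw
#' values, so the measurement itself is unsmoothed. With `m` the interior
#' minimum and `p_L`, `p_R` the highest raw values left/right of it, the
#' crossing level is `m + ((p_L + p_R)/2 - m)/2`; crossings adjacent to the
#' minimum are located by linear interpolation between the bracketing
#' samples. Exactly affine-invariant: `a*I + b` (a > 0) leaves the width
#' unchanged.
#'
#' @param profile a `transverse_profile`.
#' @param pixel_size_um calibration.
#' @return `diameter_estimate`: `fwhm_um`, `fwhm_px`, `level_half_max`,
#'   `left_px`/`right_px` (subpixel crossing offsets), `vessel_class`.
#' @export
fwhm_diameter <- function(profile, pixel_size_um) {
  stopifnot(inherits(profile, "transverse_profile"))
  assert_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  v <- profile$values
  n <- length(v)
  if (n < 5L) stop_mf("profile too short")
  sm <- stats::filter(c(v[1], v, v[n]), rep(1 / 3, 3), sides = 2)[2:(n + 1)]
  imin <- which.min(sm[2:(n - 1)]) + 1L          # interior minimum
  if (imin <= 1L || imin >= n) stop_mf("no vessel dip: monotone profile")
  m <- v[imin]
  iL <- which.max(sm[1:(imin - 1L)])
  iR <- imin + which.max(sm[(imin + 1L):n])
  pL <- v[iL]; pR <- v[iR]
  if (m >= pL || m >= pR)
    stop_mf("no vessel dip: monotone or shoulder-less profile")
  midpoint <- (pL + pR) / 2
  if (midpoint <= m) stop_mf("no vessel dip: shoulders not above minimum")
  level <- m + (midpoint - m) / 2
  cross_out <- function(side) {
    # walk outward from the minimum to the first raw crossing of `level`
    idx <- if (side < 0) seq(imin, 1L) else seq(imin, n)
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b <- idx[j + 1L]
      if ((v[a] < level) && (v[b] >= level)) {
        f <- (level - v[a]) / (v[b] - v[a])
        return(profile$positions[a] +
                 f * (profile$positions[b] - profile$positions[a]))
      }
    }
    NA_real_
  }
  left <- cross_out(-1); right <- cross_out(+1)
  if (is.na(left) || is.na(right))
    stop_mf("open profile: half-max level never crossed on one side")
  fwhm_px <- right - left
  fwhm_um <- fwhm_px * pixel_size_um
  structure(list(fwhm_um = fwhm_um, fwhm_px = fwhm_px,
                 level_half_max = level, left_px = left, right_px = right,
                 vessel_class = classify_vessel(fwhm_um)),
            class = "diameter_estimate")
}

#' @export
print.diameter_estimate <- function(x, ...) {
  cat(sprintf("diameter: %.1f um (%.2f px), class %s\n",
              x$fwhm_um, x$fwhm_px, x$vessel_class))
  if (!is.null(x$n_used))
    cat(sprintf("  aggregated over %d normal(s), %d failed\n",
                x$n_used, x$n_failed))
  invisible(x)
}

#' Classify a vessel by its diameter
#'
#' Capillary below 20 um; arteriole/vein from 20 um up to and including
#' 100 um (the 20 um boundary belongs to the upper class, since capillaries
#' are defined as strictly thinner than 20 um); out of range above 100 um.
#'
#' @param fwhm_um diameter in micrometres (> 0).
#' @return one of `"capillary"`, `"arteriole_vein"`, `"out_of_range"`.
#' @export
classify_vessel <- function(fwhm_um) {
  assert_scalar_num(fwhm_um, "fwhm_um", 0, strict_lower = TRUE)
  if (fwhm_um < 20) "capillary"
  else if (fwhm_um <= 100) "arteriole_vein"
  else "out_of_range"
}

#' Vessel diameter along a centerline
#'
#' Samples a transverse profile at every normal, measures each FWHM, and
#' aggregates by the median (robust to normals that cross a neighbouring
#' vessel or particle); normals whose profile fails (exits the frame, no dip,
#' open profile) are skipped and counted.
#'
#' @param green_frame H x W matrix (typically a static background frame of
#'   the registered window, e.g. a low temporal quantile per pixel, so
#'   passing cells do not bias the profile).
#' @param path a [centerline()].
#' @param interval_px normal spacing (default 10 px).
#' @param half_length_px profile half length (default 40 px).
#' @param pixel_size_um calibration.
#' @return a `diameter_estimate` (median aggregate) with `n_used`,
#'   `n_failed`, and `per_normal_um`.
#' @export
vessel_diameter <- function(green_frame, path, interval_px = 10,
                            half_length_px = 40, pixel_size_um) {
  normals <- compute_normals(path, interval_px)
  vals <- numeric(0)
  n_failed <- 0L
  for (nm in normals) {
    est <- tryCatch({
      pr <- sample_profile(green_frame, nm$point, nm$normal, half_length_px)
      fwhm_diameter(pr, pixel_size_um)$fwhm_um
    }, error = function(e) NA_real_)
    if (is.na(est)) n_failed <- n_failed + 1L else vals <- c(vals, est)
  }
  if (length(vals) == 0L)
    stop_mf("all %d normals failed to produce a diameter", length(normals))
  med <- stats::median(vals)
  structure(list(fwhm_um = med, fwhm_px = med / pixel_size_um,
                 level_half_max = NA_real_, left_px = NA_real_,
                 right_px = NA_real_,
                 vessel_class = classify_vessel(med),
                 n_used = length(vals), n_failed = n_failed,
                 per_normal_um = vals),
            class = "diameter_estimate")
}
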