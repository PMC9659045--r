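#' Kymograph velocimetry
#'
#' Red blood cells isolated in the sparse video trace oblique streaks in the
#' kymograph (space-time image) sampled along a vessel centerline: a cell
#' moving at v px/frame advances v columns per row, so the streak slope *is*
#' the speed. Rather than fitting individual streaks, the estimator works in
#' the Fourier domain: parallel streaks concentrate spectral energy along a
#' line through the origin orthogonal to the streak direction. With theta'
#' the angle between that dominant spectral line and the temporal-frequency
#' (v) axis, `cot(theta') = v` in px/frame, converted to um/s by
#' `pixel_size_um / frame_interval_s`. Stationary scenes give vertical
#' streaks, a dominant line along the u axis, theta' = pi/2 and velocity 0.
#'
#' @name kymo
NULL

#' Construct a kymograph object
#'
#' @param image n_time x n_space matrix: row t is the intensity along the
#'   centerline section at frame t0 + t (columns = path distance in px).
#' @param pixel_size_um,frame_interval_s calibration.
#' @param t0 first frame index (0-based) of the window.
#' @param source_id optional centerline identifier.
#' @return object of class `kymograph`.
#' @export
kymograph <- function(image, pixel_size_um, frame_interval_s, t0 = 0,
                      source_id = NA_character_) {
  image <- as.matrix(image)
  if (nrow(image) < 8L || ncol(image) < 8L)
    stop_mf("kymograph must be at least 8 x 8 (got %d x %d)",
            nrow(image), ncol(image))
  assert_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", 0,
                    strict_lower = TRUE)
  structure(list(image = image, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, t0 = t0,
                 source_id = source_id),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d px (t0 = %d)\n",
              nrow(x$image), ncol(x$image), x$t0))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(t(x$image)[, nrow(x$image):1],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  xlab = "path distance", ylab = "time", ...)
  invisible(x)
}

#' Build a kymograph along a centerline section
#'
#' Samples the (sparse) video bilinearly at equal 1-px arc-length points of
#' the section, one row per frame of the window.
#'
#' @param sparse_seq an [image_sequence()], typically from [sparse_video()].
#' @param path a [centerline()].
#' @param t0 first frame of the window (0-based).
#' @param n_frames window length; default 150 frames — the window length
#'   empirically needed for a clean dominant spectral line.
#' @param section optional `c(s0, s1)` arc-length range (px) of the path;
#'   default the whole path. Must span at least 8 px.
#' @return a [kymograph()].
#' @export
build_kymograph <- function(sparse_seq, path, t0 = 0, n_frames = 150,
                            section = NULL) {
  stopifnot(inherits(sparse_seq, "image_sequence"), inherits(path, "centerline"))
  n_total <- n_frames(sparse_seq)
  if (t0 < 0 || t0 + n_frames > n_total)
    stop_mf("frame window [%d, %d) outside sequence of %d frames",
            t0, t0 + n_frames, n_total)
  section <- section %||% c(0, max(path$arc))
  if (diff(section) < 8) stop_mf("section must span at least 8 px")
  s <- seq(section[1], section[2], by = 1)
  pts <- point_at_arc(path, s)
  img <- matrix(0, n_frames, length(s))
  for (t in seq_len(n_frames))
    img[t, ] <- bilinear_sample(green_frame(sparse_seq, t0 + t), pts[, 1],
                                pts[, 2])
  kymograph(img, sparse_seq$pixel_size_um, sparse_seq$frame_interval_s,
            t0 = t0)
}

# center-crop a matrix to N x N
center_crop_square <- function(m) {
  n <- min(dim(m))
  r0 <- (nrow(m) - n) %/% 2L
  c0 <- (ncol(m) - n) %/% 2L
  m[(r0 + 1L):(r0 + n), (c0 + 1L):(c0 + n), drop = FALSE]
}

#' Dominant spectral-line orientation of a kymograph
#'
#' The kymograph is center-cropped to a square (no resampling, so slopes stay
#' in px/frame), mean-subtracted and Hann-windowed, and its 2D FFT magnitude
#' is scanned: for each candidate angle on a 0.25 degree grid the magnitude is
#' summed along the line through the spectral origin at that angle from the
#' temporal-frequency (v) axis, within a radial band (DC and radii < 2
#' excluded). The argmax is refined by parabolic interpolation of the three
#' scores around the peak.
#'
#' @param k a [kymograph()].
#' @param band `c(r_min, r_max)` radial frequency band; default
#'   `c(2, N/2 - 1)`.
#' @param grid_deg angular grid step in degrees (default 0.25).
#' @return `spectrum_orientation`: `theta_prime_rad` in (0, pi/2] (angle from
#'   the v axis), `direction` (+1 flow toward increasing arc length, -1
#'   opposite, 0 if stationary), `energy_ratio` (dominant-line energy / band
#'   energy, a quality score; < 0.02 flags low confidence), `band`,
#'   `theta_signed_rad`, `ambiguous` (the orthogonal line carries at least
#'   half the dominant line's energy — a spectral cross, e.g. stalled flow,
#'   whose angle does not determine a speed), `low_confidence`.
#' @export
estimate_orientation <- function(k, band = NULL, grid_deg = 0.25) {
  stopifnot(inherits(k, "kymograph"))
  sq <- center_crop_square(k$image)
  N <- nrow(sq)
  band <- band %||% c(2, N / 2 - 1)
  if (band[1] < 1 || band[2] <= band[1] || band[2] > N / 2)
    stop_mf("band must satisfy 1 <= r_min < r_max <= N/2")
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(N - 1)) / (N - 1))
  win <- (sq - mean(sq)) * outer(hann, hann)
  sp <- abs(stats::fft(win))
  # fftshift: spectral origin to (ctr, ctr), 1-based (valid for odd and even N)
  idx <- ((0:(N - 1) - N %/% 2) %% N) + 1
  sp <- sp[idx, idx]
  ctr <- N %/% 2 + 1
  band_r <- pmax(band[1], 2)
  radii <- seq(band_r, band[2], by = 0.5)
  # annulus energy for the quality denominator
  rr <- sqrt(outer((1:N) - ctr, rep(1, N))^2 + outer(rep(1, N), (1:N) - ctr)^2)
  band_energy <- sum(sp[rr >= band_r & rr <= band[2]])
  if (band_energy == 0) stop_mf("no signal: zero-energy spectral band")

  # theta measured from the v (temporal frequency, row) axis; signed grid
  thetas <- seq(-90 + grid_deg, 90, by = grid_deg) * pi / 180
  score <- vapply(thetas, function(th) {
    ry <- ctr + radii * cos(th)   # row offset = v component
    rx <- ctr + radii * sin(th)   # col offset = u component
    sum(bilinear_sample(sp, ry - 1, rx - 1))  # bilinear_sample is 0-based
  }, 0)
  i <- which.max(score)
  th <- thetas[i]
  # parabolic refinement on the angular grid (wrap-aware at the ends)
  if (i > 1L && i < length(thetas)) {
    y1 <- score[i - 1]; y2 <- score[i]; y3 <- score[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) th <- th + (pi / 180 * grid_deg) * 0.5 * (y1 - y3) / den
  }
  line_energy <- score[i] * 2  # both half-lines (spectrum is symmetric)
  # a genuine streak pattern concentrates energy on one line; a spectral
  # cross (static pattern + temporal shimmer, e.g. stalled flow) puts
  # comparable energy on the orthogonal line too, and the angle is then
  # ambiguous between 0 and infinity px/frame
  th_orth <- if (th > 0) th - pi / 2 else th + pi / 2
  orth_score <- {
    ry <- ctr + radii * cos(th_orth)
    rx <- ctr + radii * sin(th_orth)
    sum(bilinear_sample(sp, ry - 1, rx - 1))
  }
  ambiguous <- orth_score >= 0.5 * score[i]
  theta_prime <- abs(th)
  if (theta_prime < 1e-9) theta_prime <- 1e-9
  structure(list(theta_prime_rad = min(theta_prime, pi / 2),
                 direction = if (abs(abs(th) - pi / 2) < 1e-9) 0
                             else -sign(th),
                 energy_ratio = line_energy / band_energy,
                 band = c(band_r, band[2]),
                 theta_signed_rad = th,
                 ambiguous = ambiguous,
                 low_confidence = ambiguous ||
                   (line_energy / band_energy) < 0.02),
            class = "spectrum_orientation")
}

#' Convert a spectral orientation into a physical velocity
#'
#' `velocity_px_per_frame = cot(theta')`; `velocity_um_s = cot(theta') *
#' pixel_size_um / frame_interval_s`.
#'
#' @param o a `spectrum_orientation`.
#' @param pixel_size_um,frame_interval_s calibration.
#' @return `velocity_estimate`: `velocity_um_s`, `velocity_px_per_frame`
#'   (both >= 0; speed), `direction`, `theta_prime_rad`, `quality`
#'   (energy ratio), `low_confidence`.
#' @export
velocity_from_angle <- function(o, pixel_size_um, frame_interval_s) {
  stopifnot(inherits(o, "spectrum_orientation"))
  assert_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", 0,
                    strict_lower = TRUE)
  th <- o$theta_prime_rad
  if (th <= 1e-9) stop_mf("unresolvable slope: theta' = 0")
  v_pxf <- 1 / tan(th)
  if (abs(th - pi / 2) < 1e-12) v_pxf <- 0
  structure(list(velocity_um_s = v_pxf * pixel_size_um / frame_interval_s,
                 velocity_px_per_frame = v_pxf,
                 direction = o$direction,
                 theta_prime_rad = th,
                 quality = o$energy_ratio,
                 low_confidence = o$low_confidence,
                 n_frames = NA_integer_),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf(
    "velocity: %.1f um/s (%.3f px/frame, theta' = %.2f deg, quality %.3f%s)\n",
    x$velocity_um_s, x$velocity_px_per_frame, x$theta_prime_rad * 180 / pi,
    x$quality, if (isTRUE(x$low_confidence)) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Estimate blood velocity along a centerline
#'
#' Composition [build_kymograph()] -> [estimate_orientation()] ->
#' [velocity_from_angle()], using the sequence's own calibration.
#'
#' @inheritParams build_kymograph
#' @param band,grid_deg passed to [estimate_orientation()].
#' @return a `velocity_estimate`.
#' @export
estimate_velocity <- function(sparse_seq, path, t0 = 0, n_frames = 150,
                              section = NULL, band = NULL, grid_deg = 0.25) {
  k <- build_kymograph(sparse_seq, path, t0, n_frames, section)
  o <- estimate_orientation(k, band, grid_deg)
  v <- velocity_from_angle(o, sparse_seq$pixel_size_um,
                           sparse_seq$frame_interval_s)
  v$n_frames <- as.integer(n_frames)
  v
}
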