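#' Synthetic microcirculation scenes
#'
#' The generator renders the scene class the analysis pipeline was designed
#' for — intravital reflectance video of the mesentery/skin: dark vessels on a
#' brighter tissue background (contrast strongest in the green channel, where
#' haemoglobin absorbs), sparse bright red-blood-cell signal advected along
#' vessel centerlines at a constant per-vessel velocity, whole-frame rigid
#' translation jitter from body motion, localized saturated disks emulating
#' residual specular reflection, and additive sensor noise. Every rendered
#' quantity is recorded as ground truth, so each downstream stage
#' (registration, segmentation, RPCA, velocimetry, diameter) has an oracle.
#'
#' @name synth
NULL

#' Specify one synthetic vessel
#'
#' @param points n x 2 matrix or list of `(x, y)` pixel coordinates (0-based)
#'   of the centerline polyline, n >= 2.
#' @param width_um vessel diameter in micrometres (> 0).
#' @param velocity_um_s signed RBC flow velocity along the polyline, um/s
#'   (sign = direction; positive runs from the first to the last point).
#' @param rbc_rate expected number of particles entering the vessel per
#'   second (>= 0).
#' @param contrast fraction in (0, 1] by which the vessel darkens the green
#'   channel relative to tissue.
#' @return `vessel_spec` list.
#' @export
vessel_spec <- function(points, width_um, velocity_um_s = 0,
                        rbc_rate = 20, contrast = 0.5) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop_mf("vessel polyline needs >= 2 (x, y) points")
  assert_scalar_num(width_um, "width_um", 0, strict_lower = TRUE)
  assert_scalar_num(rbc_rate, "rbc_rate", 0)
  assert_scalar_num(contrast, "contrast", 0, 1, strict_lower = TRUE)
  structure(list(points = points, width_um = width_um,
                 velocity_um_s = velocity_um_s, rbc_rate = rbc_rate,
                 contrast = contrast), class = "vessel_spec")
}

#' Specify a synthetic scene
#'
#' Defaults mirror the imaging rig the method targets: 0.64 um pixels, 150
#' frames (the window length the velocimetry stage uses), and a 30 fps frame
#' interval.
#'
#' @param height_px,width_px frame size in pixels.
#' @param vessels list of [vessel_spec()] objects.
#' @param tissue_level background intensity in (0, 1].
#' @param tissue_texture amplitude of the static low-pass tissue texture
#'   field (multiplicative, as a fraction of `tissue_level`); real tissue is
#'   not optically uniform, and this static structure is what frame-to-frame
#'   template matching anchors on.
#' @param noise_sd additive Gaussian noise scale.
#' @param jitter_px max per-frame rigid translation magnitude (integer px).
#' @param particle_flicker per-frame fractional amplitude fluctuation of each
#'   particle (cells rock and plasma gaps shimmer, so RBC brightness is not
#'   constant; this keeps even stationary cells visible to the
#'   low-rank/sparse separation).
#' @param specular_blobs number of saturated disks.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed; identical specs render bit-identical output.
#' @return `scene_spec` list.
#' @export
scene_spec <- function(height_px, width_px, vessels = list(),
                       tissue_level = 0.75, tissue_texture = 0.1,
                       noise_sd = 0.01, jitter_px = 0, particle_flicker = 0.15,
                       specular_blobs = 0, pixel_size_um = 0.64,
                       frame_interval_s = 1 / 30, n_frames = 150, seed = 1L) {
  assert_scalar_num(height_px, "height_px", 8)
  assert_scalar_num(width_px, "width_px", 8)
  assert_scalar_num(tissue_level, "tissue_level", 0, 1, strict_lower = TRUE)
  assert_scalar_num(tissue_texture, "tissue_texture", 0, 1)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(jitter_px, "jitter_px", 0)
  assert_scalar_num(particle_flicker, "particle_flicker", 0, 1)
  assert_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", 0,
                    strict_lower = TRUE)
  assert_scalar_num(n_frames, "n_frames", 1)
  stopifnot(is.list(vessels))
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px), vessels = vessels,
                 tissue_level = tissue_level, tissue_texture = tissue_texture,
                 noise_sd = noise_sd, particle_flicker = particle_flicker,
                 jitter_px = as.integer(jitter_px),
                 specular_blobs = as.integer(specular_blobs),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "scene_spec")
}

# distance from every grid pixel to a polyline; returns H x W matrix.
# polyline rows are (x, y).
polyline_distance <- function(h, w, poly) {
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  d2 <- matrix(Inf, h, w)
  for (i in seq_len(nrow(poly) - 1L)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1L, 1]; by <- poly[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- pmin(pmax(((X - ax) * vx + (Y - ay) * vy) / L2, 0), 1)
    d2 <- pmin(d2, (X - (ax + t * vx))^2 + (Y - (ay + t * vy))^2)
  }
  sqrt(d2)
}

# add an isotropic Gaussian bright blob at subpixel (y, x) into matrix m
add_blob <- function(m, y, x, sigma, amp) {
  h <- nrow(m); w <- ncol(m)
  r <- ceiling(3 * sigma)
  r0 <- max(0, floor(y) - r); r1 <- min(h - 1, ceiling(y) + r)
  c0 <- max(0, floor(x) - r); c1 <- min(w - 1, ceiling(x) + r)
  if (r0 > r1 || c0 > c1) return(m)
  yy <- r0:r1; xx <- c0:c1
  g <- outer(exp(-(yy - y)^2 / (2 * sigma^2)),
             exp(-(xx - x)^2 / (2 * sigma^2)))
  m[yy + 1, xx + 1] <- m[yy + 1, xx + 1] + amp * g
  m
}

#' Render a synthetic microcirculation video with ground truth
#'
#' The static scene (tissue, darkened vessels, specular disks) is rendered
#' once; per frame, bright Gaussian particles (sigma = width/4, the rendered
#' RBC signal) are advected along each centerline at the vessel's constant
#' velocity, the whole frame is translated by an integer jitter shift (edge
#' replication), and Gaussian noise is added. Vessel edges taper over ~1 px
#' (a Gaussian edge profile whose half-darkening point sits exactly at the
#' nominal radius, so the FWHM of the transverse profile equals `width_um`).
#' Frames are quantized to the 16-bit grid so disk round trips are bit-exact.
#'
#' @param spec a [scene_spec()].
#' @return list with `seq` (an [image_sequence()], RGB) and `truth`, a list:
#'   `vessel_mask` (binary H x W), `centerlines` (list of [centerline()]),
#'   `velocity_um_s`, `width_um` (per vessel), `shifts` (n_frames x 2 matrix
#'   of applied (dy, dx)), `particles` (per frame, matrix of (y, x) particle
#'   centers in jittered frame coordinates).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height_px; w <- spec$width_px; n <- spec$n_frames
  px <- spec$pixel_size_um; dt <- spec$frame_interval_s

  for (v in spec$vessels) {
    if (any(v$points[, 1] < 0) || any(v$points[, 1] > w - 1) ||
        any(v$points[, 2] < 0) || any(v$points[, 2] > h - 1))
      stop_mf("geometry error: vessel polyline exits the %d x %d frame", h, w)
  }

  with_seed(spec$seed, {
    tex <- if (spec$tissue_texture > 0) {
      k <- gauss_kernels(1)$g
      raw <- matrix(stats::rnorm(h * w), h, w)
      sm <- EBImage::filter2(raw, outer(k, k), boundary = "replicate")
      # unit-variance field scaled by the texture amplitude (values beyond
      # [0, 1] are clipped at frame assembly)
      1 + spec$tissue_texture * sm / stats::sd(sm)
    } else 1
    base_g <- matrix(spec$tissue_level, h, w) * tex
    base_rb <- matrix(spec$tissue_level, h, w) * tex
    mask <- matrix(0L, h, w)
    centerlines <- list()
    edge_sigma <- 1.0
    for (v in spec$vessels) {
      d <- polyline_distance(h, w, v$points)
      half_w <- (v$width_um / px) / 2
      k <- stats::pnorm((half_w - d) / edge_sigma)  # 0.5 exactly at radius
      base_g <- base_g * (1 - v$contrast * k)
      base_rb <- base_rb * (1 - 0.5 * v$contrast * k)
      mask[d <= half_w] <- 1L
      cl_pts <- v$points[, c(2, 1), drop = FALSE]  # to (y, x)
      centerlines[[length(centerlines) + 1L]] <-
        resample_centerline(centerline(cl_pts), spacing = 1)
    }

    if (spec$specular_blobs > 0) {
      spec_y <- stats::runif(spec$specular_blobs, 0, h - 1)
      spec_x <- stats::runif(spec$specular_blobs, 0, w - 1)
      spec_r <- stats::runif(spec$specular_blobs, 2, 4)
    }

    # particle schedules: entry time (frames) and entry arc position
    schedules <- lapply(seq_along(spec$vessels), function(i) {
      v <- spec$vessels[[i]]
      cl <- centerlines[[i]]
      L <- arc_length(cl)
      v_pxf <- v$velocity_um_s * dt / px   # px per frame
      if (abs(v_pxf) > 1e-12) {
        span <- n + L / abs(v_pxf)
        cnt <- stats::rpois(1, v$rbc_rate * dt * span)
        t_entry <- stats::runif(cnt, -L / abs(v_pxf), n)
        s0 <- rep(if (v_pxf > 0) 0 else L, cnt)
      } else {
        cnt <- stats::rpois(1, v$rbc_rate * dt * n)
        t_entry <- rep(0, cnt)
        s0 <- stats::runif(cnt, 0, L)
      }
      # blob scale: a quarter of the vessel width, capped at the physical
      # RBC size (~7 um -> sigma ~3 px at 0.64 um/px)
      list(t_entry = t_entry, s0 = s0, v_pxf = v_pxf, L = L, cl = cl,
           sigma = min(max(0.8, (v$width_um / px) / 4), 3))
    })

    shifts <- matrix(0L, n, 2)  # (dy, dx)
    if (spec$jitter_px > 0 && n > 1)
      shifts[2:n, ] <- matrix(
        as.integer(sample(-spec$jitter_px:spec$jitter_px,
                          2L * (n - 1L), replace = TRUE)), n - 1L, 2)

    frames <- array(0, dim = c(h, w, 3L, n))
    particles <- vector("list", n)
    amp <- 0.2  # RBC signal is subtle pre-decomposition; RPCA isolates it
    for (t in seq_len(n)) {
      g <- base_g; rb <- base_rb
      pts_t <- matrix(numeric(0), 0, 2)
      for (sch in schedules) {
        s <- sch$s0 + sch$v_pxf * ((t - 1) - sch$t_entry)
        if (abs(sch$v_pxf) <= 1e-12) s <- sch$s0
        ok <- s >= 0 & s <= sch$L
        if (!any(ok)) next
        pos <- point_at_arc(sch$cl, s[ok])
        fl <- if (spec$particle_flicker > 0)
          pmax(1 + spec$particle_flicker * stats::rnorm(nrow(pos)), 0.2)
        else rep(1, nrow(pos))
        for (j in seq_len(nrow(pos))) {
          g <- add_blob(g, pos[j, 1], pos[j, 2], sch$sigma, amp * fl[j])
          rb <- add_blob(rb, pos[j, 1], pos[j, 2], sch$sigma, amp * fl[j] / 2)
        }
        pts_t <- rbind(pts_t, pos)
      }
      if (spec$specular_blobs > 0) {
        X <- matrix(rep(0:(w - 1), each = h), h, w)
        Y <- matrix(rep(0:(h - 1), times = w), h, w)
        for (b in seq_len(spec$specular_blobs)) {
          disk <- (X - spec_x[b])^2 + (Y - spec_y[b])^2 <= spec_r[b]^2
          g[disk] <- 1; rb[disk] <- 1
        }
      }
      dy <- shifts[t, 1]; dx <- shifts[t, 2]
      if (dy != 0 || dx != 0) {
        g <- shift_matrix(g, dy, dx)
        rb <- shift_matrix(rb, dy, dx)
        if (nrow(pts_t)) pts_t <- pts_t + matrix(c(dy, dx), nrow(pts_t), 2,
                                                 byrow = TRUE)
      }
      if (spec$noise_sd > 0) {
        g <- g + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
        rb <- rb + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      }
      frames[, , 1, t] <- pmin(pmax(rb, 0), 1)
      frames[, , 2, t] <- pmin(pmax(g, 0), 1)
      frames[, , 3, t] <- frames[, , 1, t]
      particles[[t]] <- pts_t
    }
    frames <- round(frames * 65535) / 65535  # 16-bit grid: lossless round trip

    list(seq = image_sequence(frames, px, dt, bit_depth = 16L),
         truth = list(
           vessel_mask = mask,
           centerlines = centerlines,
           velocity_um_s = vapply(spec$vessels, `[[`, 0, "velocity_um_s"),
           width_um = vapply(spec$vessels, `[[`, 0, "width_um"),
           shifts = shifts,
           particles = particles))
  })
}

#' Render a synthetic kymograph with known streak slope
#'
#' Direct synthesis of the space-time image the velocimetry stage analyses:
#' bright Gaussian-profile streaks of exact slope `velocity_px_per_frame`
#' (columns of path distance, rows of time) plus optional Gaussian noise.
#'
#' @param velocity_px_per_frame streak slope: px of path distance per frame
#'   (signed).
#' @param n_space,n_time kymograph size (both >= 8).
#' @param streak_width_px Gaussian sigma of a streak's transverse profile.
#' @param streak_rate expected number of new streaks per frame.
#' @param noise_sd additive noise scale.
#' @param seed RNG seed.
#' @param pixel_size_um,frame_interval_s calibration attached to the result.
#' @return a `kymograph` object (see [build_kymograph()]).
#' @export
render_kymograph <- function(velocity_px_per_frame, n_space, n_time,
                             streak_width_px = 1.5, streak_rate = 0.2,
                             noise_sd = 0, seed = 1L,
                             pixel_size_um = 1, frame_interval_s = 1) {
  if (n_space < 8 || n_time < 8) stop_mf("n_space and n_time must be >= 8")
  v <- velocity_px_per_frame
  with_seed(seed, {
    lo <- min(0, -v * n_time) - 3 * streak_width_px
    hi <- max(n_space, n_space - v * n_time) + 3 * streak_width_px
    cnt <- max(3L, stats::rpois(1, streak_rate * (hi - lo) /
                                     max(1, abs(v) + 1)))
    cnt <- max(cnt, ceiling(streak_rate * n_time))
    c0 <- stats::runif(cnt, lo, hi)
    tt <- 0:(n_time - 1); xx <- 0:(n_space - 1)
    img <- matrix(0, n_time, n_space)
    for (ck in c0) {
      # streak center column at row t: ck + v t
      ctr <- ck + v * tt
      img <- img + exp(-outer(-ctr, xx, `+`)^2 / (2 * streak_width_px^2))
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          n_time, n_space)
    kymograph(img, pixel_size_um, frame_interval_s, t0 = 0)
  })
}

#' Simulate a longitudinal cohort
#'
#' Emulates the study design the statistics layer targets: groups of subjects
#' (rats) each measured at a shared grid of timepoints, with a per-group mean
#' trend plus independent Gaussian noise. Used to test summaries,
#' normalization and the per-timepoint paired t-tests against baseline.
#'
#' @param group_effects named list: group name -> numeric vector of mean
#'   values, one per timepoint.
#' @param n_rats subjects per group (>= 2).
#' @param timepoints numeric vector of timepoints (hours); non-empty.
#' @param noise_sd per-observation Gaussian noise.
#' @param seed RNG seed.
#' @param quantity quantity label for the records.
#' @return data.frame with columns `group`, `subject_id`, `timepoint_h`,
#'   `quantity`, `value`.
#' @export
simulate_cohort <- function(group_effects, n_rats = 5, timepoints,
                            noise_sd = 0, seed = 1L,
                            quantity = "velocity_um_s") {
  if (length(timepoints) == 0L) stop_mf("timepoints must be non-empty")
  if (n_rats < 2) stop_mf("n_rats must be >= 2")
  stopifnot(is.list(group_effects), !is.null(names(group_effects)))
  for (g in names(group_effects))
    if (length(group_effects[[g]]) != length(timepoints))
      stop_mf("group '%s' trend length != number of timepoints", g)
  with_seed(seed, {
    rows <- list()
    for (g in names(group_effects)) {
      trend <- group_effects[[g]]
      for (r in seq_len(n_rats)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g,
          subject_id = sprintf("%s_rat%02d", g, r),
          timepoint_h = timepoints,
          quantity = quantity,
          value = trend + stats::rnorm(length(timepoints), 0, noise_sd))
      }
    }
    do.call(rbind, rows)
  })
}
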