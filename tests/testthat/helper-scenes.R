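# Shared fixture builders. All fixtures are generated in code at test time.

# straight horizontal vessel centred at row y0; defaults give an
# arteriole-class vessel (25 um) with sparse RBC traffic
straight_scene <- function(velocity_um_s = 100, width_um = 25, rbc_rate = 10,
                           noise_sd = 0.01, jitter_px = 2, n_frames = 150,
                           seed = 1, height_px = 72, width_px = 170,
                           y0 = 30, ...) {
  scene_spec(height_px, width_px,
             list(vessel_spec(rbind(c(4, y0), c(width_px - 5, y0)),
                              width_um = width_um,
                              velocity_um_s = velocity_um_s,
                              rbc_rate = rbc_rate)),
             noise_sd = noise_sd, jitter_px = jitter_px,
             n_frames = n_frames, seed = seed, ...)
}

default_cfg <- function(...) {
  run_config(pixel_size_um = 0.64, frame_interval_s = 1 / 30,
             search_radius_px = 3, vesselness_scales = c(2, 4, 8, 16),
             diam_half_length_px = 28, ...)
}

# profile over a 1D intensity function: a tiny image whose rows repeat f
profile_from_values <- function(values) {
  img <- matrix(rep(values, each = 3), nrow = 3)
  half <- (length(values) - 1L) %/% 2L
  sample_profile(img, point = c(1, half), normal = c(0, 1),
                 half_length_px = half)
}

# planted low-rank + sparse matrix with known decomposition
planted_lowrank_sparse <- function(m, n, rank = 2, sparsity = 0.05,
                                   seed = 1) {
  set.seed(seed)
  U <- matrix(rnorm(m * rank), m) / sqrt(m)
  V <- matrix(rnorm(n * rank), n) / sqrt(n)
  L0 <- 10 * U %*% t(V)
  S0 <- matrix(0, m, n)
  idx <- sample(m * n, round(sparsity * m * n))
  S0[idx] <- sample(c(-1, 1), length(idx), TRUE) * runif(length(idx), 0.5, 1)
  list(L = L0, S = S0, D = L0 + S0, idx = idx)
}

# brute-force orientation oracle: rotate the kymograph over an angle grid and
# maximise the variance of column means (streaks aligned with columns give
# the most column-structured image); independent of the spectral estimator.
rotate_bilinear <- function(img, angle_rad) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  yy <- matrix(rep(0:(h - 1), times = w), h, w) - cy
  xx <- matrix(rep(0:(w - 1), each = h), h, w) - cx
  ys <- cy + yy * cos(angle_rad) - xx * sin(angle_rad)
  xs <- cx + yy * sin(angle_rad) + xx * cos(angle_rad)
  matrix(microflow:::bilinear_sample(img, as.vector(ys), as.vector(xs)), h, w)
}

oracle_streak_angle <- function(kymo_img, coarse_deg = 1, fine_deg = 0.05) {
  sq <- microflow:::center_crop_square(kymo_img)
  colvar <- function(a_deg) {
    rot <- rotate_bilinear(sq, a_deg * pi / 180)
    stats::var(colMeans(rot))
  }
  # streaks at angle a from the vertical become vertical when rotated by -a;
  # scan the signed streak angle from the time axis
  grid <- seq(-89, 89, by = coarse_deg)
  v <- vapply(grid, colvar, 0)
  best <- grid[which.max(v)]
  fine <- seq(best - coarse_deg, best + coarse_deg, by = fine_deg)
  vf <- vapply(fine, colvar, 0)
  fine[which.max(vf)]
}
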