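test_that("identical scene specs render bit-identical output", {
  sp <- straight_scene(n_frames = 6, seed = 9)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$truth, b$truth)
})

test_that("seed changes particles but not geometry", {
  a <- render_scene(straight_scene(n_frames = 4, seed = 1))
  b <- render_scene(straight_scene(n_frames = 4, seed = 2))
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  expect_false(identical(a$seq$frames, b$seq$frames))
})

test_that("a static scene renders identical constant frames", {
  sp <- scene_spec(32, 32, vessels = list(), tissue_level = 0.6,
                   tissue_texture = 0, noise_sd = 0, jitter_px = 0,
                   n_frames = 4, seed = 1)
  rs <- render_scene(sp)
  expect_equal(max(abs(rs$seq$frames - round(0.6 * 65535) / 65535)), 0)
  for (t in 2:4)
    expect_identical(get_frame(rs$seq, t), get_frame(rs$seq, 1))
})

test_that("vessel polylines exiting the frame are rejected", {
  v <- vessel_spec(rbind(c(-3, 10), c(40, 10)), width_um = 10)
  expect_error(render_scene(scene_spec(32, 32, list(v), n_frames = 1)),
               "geometry")
})

test_that("rendered particle centroids advance at the calibrated speed", {
  # 100 um/s, 0.64 um/px, 1/30 s/frame -> 5.208 px/frame along the vessel
  sp <- straight_scene(velocity_um_s = 100, rbc_rate = 2, noise_sd = 0,
                       jitter_px = 0, tissue_texture = 0, n_frames = 40,
                       seed = 4)
  rs <- render_scene(sp)
  static <- render_scene(straight_scene(velocity_um_s = 100, rbc_rate = 0,
                                        noise_sd = 0, jitter_px = 0,
                                        tissue_texture = 0, n_frames = 1,
                                        seed = 4))
  base <- green_frame(static$seq, 1)
  v_pxf <- 100 * (1 / 30) / 0.64
  # frames with exactly one particle well inside the frame
  centroid_x <- rep(NA_real_, 40)
  for (t in 1:40) {
    p <- rs$truth$particles[[t]]
    if (nrow(p) == 1 && p[1, 2] > 15 && p[1, 2] < 150) {
      d <- green_frame(rs$seq, t) - base
      d[d < 0.02] <- 0
      if (sum(d) > 0)
        centroid_x[t] <- sum(d * col(d)) / sum(d) - 1
    }
  }
  steps <- diff(centroid_x)
  steps <- steps[!is.na(steps)]
  expect_gt(length(steps), 3)
  expect_true(all(abs(steps - v_pxf) < 0.2))
})

test_that("every ground-truth centerline point lies inside the vessel mask", {
  for (seed in 1:3) {
    sp <- scene_spec(90, 120, list(
      vessel_spec(rbind(c(10, 20), c(110, 70)), width_um = 18,
                  velocity_um_s = 50),
      vessel_spec(rbind(c(15, 80), c(100, 80)), width_um = 10)),
      n_frames = 2, seed = seed)
    rs <- render_scene(sp)
    for (cl in rs$truth$centerlines) {
      idx <- cbind(round(cl$points[, 1]) + 1, round(cl$points[, 2]) + 1)
      expect_true(all(rs$truth$vessel_mask[idx] == 1))
    }
  }
})

test_that("rendered kymograph streaks have the requested slope", {
  # v = 0: stationary bright columns (all rows identical)
  k0 <- render_kymograph(0, 32, 20, noise_sd = 0, seed = 1)
  for (t in 2:20) expect_equal(k0$image[t, ], k0$image[1, ])
  # v = 1: shifting a row by one column reproduces the next row (45 degrees)
  k1 <- render_kymograph(1, 48, 20, noise_sd = 0, seed = 1)
  for (t in 1:19)
    expect_equal(k1$image[t + 1, 2:48], k1$image[t, 1:47], tolerance = 1e-10)
})

test_that("simulated cohorts follow the requested trends", {
  tp <- c(-1, 2, 4, 6)
  eff <- list(sham = c(200, 200, 200, 200), clp = c(200, 150, 120, 100))
  tab <- simulate_cohort(eff, n_rats = 5, timepoints = tp, noise_sd = 0,
                         seed = 3)
  expect_equal(nrow(tab), 2 * 5 * 4)
  for (g in names(eff)) for (i in seq_along(tp)) {
    v <- tab$value[tab$group == g & tab$timepoint_h == tp[i]]
    expect_equal(unique(v), eff[[g]][i])
  }
  expect_error(simulate_cohort(eff, 5, numeric(0)), "timepoints")
  expect_identical(tab, simulate_cohort(eff, 5, tp, 0, seed = 3))
})
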