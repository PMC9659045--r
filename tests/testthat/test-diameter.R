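test_that("normals are perpendicular to the path at regular intervals", {
  horiz <- centerline(cbind(rep(10, 60), 0:59))
  nms <- compute_normals(horiz, 10)
  expect_length(nms, 6)
  for (nm in nms) {
    expect_equal(abs(nm$normal[1]), 1, tolerance = 1e-9)
    expect_equal(nm$normal[2], 0, tolerance = 1e-9)
  }
  # circle arc: normals point radially
  th <- seq(0, pi / 2, length.out = 200)
  circ <- centerline(cbind(50 - 40 * cos(th), 10 + 40 * sin(th)))
  for (nm in compute_normals(circ, 15)) {
    radial <- (nm$point - c(50, 10)) / sqrt(sum((nm$point - c(50, 10))^2))
    expect_gte(abs(sum(nm$normal * radial)), 0.99)
  }
  # interval equal to the whole arc: a single normal at the start
  expect_length(compute_normals(horiz, arc_length(horiz)), 1)
  expect_error(compute_normals(horiz, 100), "shorter")
})

test_that("profiles sample bilinearly along the normal", {
  img <- matrix(0.7, 30, 30)
  pr <- sample_profile(img, c(15, 15), c(1, 0), 10)
  expect_length(pr$values, 21)
  expect_true(all(pr$values == 0.7))
  expect_equal(pr$center_index, 11L)
  # dark vertical band crossing the profile center
  img2 <- matrix(1, 30, 30); img2[, 14:18] <- 0.3; img2[, 16] <- 0.1
  pr2 <- sample_profile(img2, c(15, 15), c(0, 1), 10)
  expect_lte(abs(which.min(pr2$values) - pr2$center_index), 1)
  # non-unit normals are normalized internally
  pr3 <- sample_profile(img2, c(15, 15), c(0, 7), 10)
  expect_equal(pr3$values, pr2$values)
  expect_error(sample_profile(img, c(2, 15), c(1, 0), 10), "exits frame")
})

test_that("rectangular dips give exactly their width", {
  for (w in c(5, 11, 20)) {
    n_side <- 30
    vals <- c(rep(0.8, n_side), rep(0.2, w), rep(0.8, n_side))
    if (length(vals) %% 2 == 0) vals <- c(vals, 0.8)
    est <- fwhm_diameter(profile_from_values(vals), pixel_size_um = 1)
    expect_equal(est$fwhm_px, w, tolerance = 1e-9)
  }
})

test_that("Gaussian dips give the analytic FWHM of 2 sqrt(2 ln 2) sigma", {
  for (sigma in c(2, 4, 8, 16)) {
    half <- ceiling(5 * sigma)
    x <- (-half):half
    vals <- 0.9 - 0.5 * exp(-x^2 / (2 * sigma^2))
    est <- fwhm_diameter(profile_from_values(vals), pixel_size_um = 1)
    expect_equal(est$fwhm_px, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.25 /
                   (2 * sqrt(2 * log(2)) * sigma))
    # crossing oracle: 100x oversampled linear interpolation of the profile
    fine_x <- seq(-half, half, by = 0.01)
    fine <- stats::approx(x, vals, xout = fine_x)$y
    lv <- est$level_half_max
    left_or <- fine_x[min(which(fine_x < 0 & fine < lv))]
    right_or <- fine_x[max(which(fine_x > 0 & fine < lv))]
    expect_lte(abs(est$left_px - left_or), 0.05)
    expect_lte(abs(est$right_px - right_or), 0.05)
  }
})

test_that("asymmetric shoulders use the midpoint-of-peaks level", {
  vals <- c(seq(100, 40, length.out = 21), seq(40, 80, length.out = 21)[-1])
  est <- fwhm_diameter(profile_from_values(vals), pixel_size_um = 1)
  # m = 40, pL = 100, pR = 80 -> level = 40 + ((90 - 40) / 2) = 65
  expect_equal(est$level_half_max, 65)
})

test_that("FWHM is exactly invariant to positive affine intensity maps", {
  x <- (-40):40
  vals <- 0.8 - 0.45 * exp(-x^2 / 72)
  a <- fwhm_diameter(profile_from_values(vals), 0.64)
  b <- fwhm_diameter(profile_from_values(3.7 * vals + 12), 0.64)
  expect_equal(a$fwhm_px, b$fwhm_px, tolerance = 1e-12)
})

test_that("degenerate profiles raise the documented errors", {
  expect_error(fwhm_diameter(profile_from_values(seq(0, 1, length.out = 21)),
                             1), "dip")
  # dip at the edge: level never crossed on the outer side
  vals <- c(seq(0.2, 0.9, length.out = 41))
  vals[1:3] <- 0.1
  expect_error(fwhm_diameter(profile_from_values(vals), 1), "open|dip")
})

test_that("vessels classify at the 20 and 100 um boundaries", {
  expect_equal(classify_vessel(19.9), "capillary")
  expect_equal(classify_vessel(20.0), "arteriole_vein")
  expect_equal(classify_vessel(100.0), "arteriole_vein")
  expect_equal(classify_vessel(100.1), "out_of_range")
  expect_equal(classify_vessel(150), "out_of_range")
  expect_error(classify_vessel(0), "fwhm_um")
})

test_that("scene diameters are recovered and classified from ground truth", {
  # 30 um arteriole
  rs <- render_scene(straight_scene(width_um = 30, rbc_rate = 0,
                                    noise_sd = 0.005, jitter_px = 0,
                                    n_frames = 1, seed = 6))
  d <- vessel_diameter(green_frame(rs$seq, 1), rs$truth$centerlines[[1]],
                       10, 30, 0.64)
  expect_equal(d$fwhm_um, 30, tolerance = 2 / 30)
  expect_equal(d$vessel_class, "arteriole_vein")
  # 12 um capillary
  rc <- render_scene(straight_scene(width_um = 12, rbc_rate = 0,
                                    noise_sd = 0.005, jitter_px = 0,
                                    n_frames = 1, seed = 7))
  dc <- vessel_diameter(green_frame(rc$seq, 1), rc$truth$centerlines[[1]],
                        10, 25, 0.64)
  expect_equal(dc$vessel_class, "capillary")
  # monotone width sweep
  est <- vapply(c(8, 16, 30, 45, 60), function(w) {
    r <- render_scene(straight_scene(width_um = w, rbc_rate = 0,
                                     noise_sd = 0.005, jitter_px = 0,
                                     n_frames = 1, height_px = 120, y0 = 55,
                                     seed = 8))
    vessel_diameter(green_frame(r$seq, 1), r$truth$centerlines[[1]],
                    10, 52, 0.64)$fwhm_um
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("diameter is rotation invariant within half a pixel", {
  w_um <- 20
  rs_h <- render_scene(straight_scene(width_um = w_um, rbc_rate = 0,
                                      noise_sd = 0, jitter_px = 0,
                                      tissue_texture = 0, n_frames = 1,
                                      height_px = 120, width_px = 120,
                                      y0 = 60, seed = 9))
  d_h <- vessel_diameter(green_frame(rs_h$seq, 1),
                         rs_h$truth$centerlines[[1]], 8, 35, 1)
  # same vessel at 30 degrees
  ang <- 30 * pi / 180
  cx <- 60; cy <- 60; L <- 55
  p1 <- c(cx - L * cos(ang), cy - L * sin(ang))
  p2 <- c(cx + L * cos(ang), cy + L * sin(ang))
  sp_r <- scene_spec(120, 120, list(vessel_spec(rbind(p1, p2),
                                                width_um = w_um)),
                     tissue_texture = 0, noise_sd = 0, jitter_px = 0,
                     n_frames = 1, seed = 9)
  rs_r <- render_scene(sp_r)
  d_r <- vessel_diameter(green_frame(rs_r$seq, 1),
                         rs_r$truth$centerlines[[1]], 8, 35, 1)
  expect_lt(abs(d_h$fwhm_px - d_r$fwhm_px), 0.5)
})
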