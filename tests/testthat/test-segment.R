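test_that("vesselness is zero on constant input and peaks on the centerline", {
  expect_equal(enhance_vessels(matrix(0.5, 40, 40), c(2, 4)),
               matrix(0, 40, 40))
  # dark straight vessel (20 px wide): with the matched scale ~ w/2 included,
  # the ridge of maximal response runs along the true centerline
  rs <- render_scene(straight_scene(rbc_rate = 0, noise_sd = 0, jitter_px = 0,
                                    tissue_texture = 0, n_frames = 1,
                                    width_um = 12.8, seed = 1))
  g <- green_frame(rs$seq, 1)
  enh <- enhance_vessels(g, c(10, 16))
  for (cc in seq(20, 150, by = 10))
    expect_lte(abs(which.max(enh[, cc]) - 1 - 30), 1)
  # polarity: a bright (inverted) vessel must not respond
  enh_inv <- enhance_vessels(max(g) + min(g) - g, c(10, 16))
  band <- enh_inv[26:36, 20:150]
  expect_lt(mean(band), 0.05)
})

test_that("segmentation thresholds and cleans the enhancement image", {
  z <- matrix(0, 20, 20)
  expect_equal(segment_vessels(z, enhancement = z, threshold = 0.5,
                               min_object_px = 0), matrix(0L, 20, 20))
  e <- matrix(0.8, 10, 10)
  expect_equal(sum(segment_vessels(e, enhancement = e, threshold = 0.9,
                                   min_object_px = 0)), 0)
  expect_equal(sum(segment_vessels(e, enhancement = e, threshold = 0.5,
                                   min_object_px = 0)), 100)
})

test_that("patch extraction covers every pixel with border-anchored origins", {
  img <- matrix(runif(256 * 256), 256, 256)
  p1 <- extract_patches(img, 256, 256)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$origin, c(0, 0))
  img2 <- matrix(runif(300 * 300), 300, 300)
  p2 <- extract_patches(img2, 256, 128)
  expect_setequal(unique(vapply(p2, function(p) p$origin[1], 0)), c(0, 44))
  expect_setequal(unique(vapply(p2, function(p) p$origin[2], 0)), c(0, 44))
  # brute-force coverage oracle on assorted sizes
  for (dims in list(c(17, 23, 8, 3), c(20, 20, 8, 8), c(9, 31, 5, 4))) {
    im <- matrix(0, dims[1], dims[2])
    ps <- extract_patches(im, dims[3], dims[4])
    cov <- matrix(0, dims[1], dims[2])
    for (p in ps)
      cov[p$origin[1] + 1:dims[3], p$origin[2] + 1:dims[3]] <-
        cov[p$origin[1] + 1:dims[3], p$origin[2] + 1:dims[3]] + 1
    expect_true(all(cov >= 1))
  }
  expect_error(extract_patches(img, 64, 65), "stride")
})

test_that("extract then stitch is the identity; overlaps average", {
  img <- matrix(runif(40 * 56), 40, 56)
  for (stride in c(8, 5, 16)) {
    ps <- extract_patches(img, 16, stride)
    expect_identical(stitch_patches(ps, dim(img)), img)
  }
  two <- list(list(patch = matrix(0, 4, 4), origin = c(0, 0)),
              list(patch = matrix(1, 4, 4), origin = c(0, 2)))
  st <- stitch_patches(two, c(4, 6))
  expect_equal(st[, 3:4], matrix(0.5, 4, 2))
  # brute-force per-pixel sum/count oracle on a random patch set
  set.seed(42)
  ps <- lapply(1:12, function(i)
    list(patch = matrix(runif(25), 5, 5),
         origin = c(sample(0:7, 1), sample(0:7, 1))))
  acc <- matrix(0, 12, 12); cnt <- matrix(0, 12, 12)
  for (p in ps) {
    ry <- p$origin[1] + 1:5; rx <- p$origin[2] + 1:5
    acc[ry, rx] <- acc[ry, rx] + p$patch; cnt[ry, rx] <- cnt[ry, rx] + 1
  }
  if (all(cnt >= 1))
    expect_equal(stitch_patches(ps, c(12, 12)), acc / cnt)
  expect_error(stitch_patches(list(list(patch = matrix(1, 2, 2),
                                        origin = c(0, 0))), c(5, 5)),
               "uncovered")
})

test_that("segmentation metrics match brute-force confusion counts", {
  expect_equal(evaluate_segmentation(diag(4), diag(4)),
               list(accuracy = 1, recall = 1, specificity = 1))
  m <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(evaluate_segmentation(1 - m, m),
               list(accuracy = 0, recall = 0, specificity = 0))
  set.seed(7)
  for (i in 1:25) {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    truth <- matrix(rbinom(64, 1, 0.5), 8, 8)
    tp <- tn <- fp <- fn <- 0
    for (r in 1:8) for (cc in 1:8) {
      if (pred[r, cc] == 1 && truth[r, cc] == 1) tp <- tp + 1
      if (pred[r, cc] == 0 && truth[r, cc] == 0) tn <- tn + 1
      if (pred[r, cc] == 1 && truth[r, cc] == 0) fp <- fp + 1
      if (pred[r, cc] == 0 && truth[r, cc] == 1) fn <- fn + 1
    }
    m <- evaluate_segmentation(pred, truth)
    expect_equal(m$accuracy, (tp + tn) / 64)
    expect_equal(m$recall, if (tp + fn == 0) NA_real_ else tp / (tp + fn))
    expect_equal(m$specificity,
                 if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  }
  expect_error(evaluate_segmentation(diag(3), diag(4)), "mismatch")
})

test_that("thinning yields a thin, contained, idempotent skeleton", {
  bar <- matrix(0L, 9, 100); bar[3:7, ] <- 1L
  sk <- skeletonize(bar)
  # interior columns reduce to a single pixel on the symmetric midline
  expect_true(all(colSums(sk[, 5:96]) == 1))
  expect_true(all(sk[5, 5:96] == 1))
  expect_equal(skeletonize(matrix(0L, 5, 5)), matrix(0L, 5, 5))
  rs <- render_scene(straight_scene(rbc_rate = 0, noise_sd = 0,
                                    jitter_px = 0, n_frames = 1, seed = 2))
  mask <- rs$truth$vessel_mask
  sk2 <- skeletonize(mask)
  expect_true(all(mask[sk2 == 1L] == 1L))      # skeleton subset of mask
  expect_identical(skeletonize(sk2), sk2)      # idempotence
  # skeleton stays within 1 px of the true centerline row
  pos <- which(sk2 == 1L, arr.ind = TRUE)
  interior <- pos[pos[, 2] > 10 & pos[, 2] < 160, , drop = FALSE]
  expect_lte(max(abs(interior[, 1] - 1 - 30)), 1)
})

test_that("centerline tracing walks endpoint to branch with unit tangents", {
  sk <- matrix(0L, 7, 60); sk[4, 6:55] <- 1L
  path <- trace_centerline(sk, c(3, 5))
  expect_equal(length(path), 50)
  expect_equal(arc_length(path), 49)
  expect_true(all(abs(path$tangents[, 1]) < 1e-9))
  expect_true(all(abs(path$tangents[, 2] - 1) < 1e-9))
  expect_true(all(abs(sqrt(rowSums(path$tangents^2)) - 1) < 1e-9))
  # an L-corner of degree 2 is walked through, not stopped at
  skL <- matrix(0L, 30, 30)
  skL[5, 5:20] <- 1L; skL[5:20, 20] <- 1L
  pL <- trace_centerline(skL, c(4, 4), smooth = FALSE)
  expect_equal(length(pL), 16 + 15)
  # degree-0 and degree-2 starts are rejected
  iso <- matrix(0L, 5, 5); iso[3, 3] <- 1L
  expect_error(trace_centerline(iso, c(2, 2)), "degree 1")
  expect_error(trace_centerline(sk, c(3, 10)), "degree 1")
  expect_error(trace_centerline(sk, c(0, 0)), "not a skeleton pixel")
})

test_that("branch-free segments are recovered from a T-shaped skeleton", {
  sk <- matrix(0L, 40, 40)
  sk[20, 2:38] <- 1L
  sk[2:19, 20] <- 1L
  paths <- centerline_paths(sk, min_length_px = 10)
  expect_equal(length(paths), 3)
})

test_that("synthetic scenes segment with high recall and specificity", {
  # regime check across thin and thick vessels at the default threshold
  for (w_um in c(6.4, 16, 32)) {
    rs <- render_scene(straight_scene(width_um = w_um, rbc_rate = 0,
                                      noise_sd = 0.005, jitter_px = 0,
                                      n_frames = 1, height_px = 120, y0 = 55,
                                      seed = 5))
    g <- green_frame(rs$seq, 1)
    mask <- segment_vessels(g, enhance_vessels(g, c(2, 4, 8, 16)),
                            threshold = 0.15, min_object_px = 50)
    m <- evaluate_segmentation(mask, rs$truth$vessel_mask)
    expect_gte(m$recall, 0.8)
    expect_gte(m$specificity, 0.95)
  }
})

test_that("a patch predictor can be plugged into segmentation", {
  rs <- render_scene(straight_scene(rbc_rate = 0, noise_sd = 0, jitter_px = 0,
                                    n_frames = 1, seed = 3))
  g <- green_frame(rs$seq, 1)
  # trivial probabilistic predictor: darker than patch mean -> vessel
  pred <- function(patch) (patch < mean(patch) - 0.05) * 1
  mask <- segment_vessels(g, predictor = pred, threshold = 0.5,
                          min_object_px = 50)
  m <- evaluate_segmentation(mask, rs$truth$vessel_mask)
  expect_gte(m$recall, 0.8)
})
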