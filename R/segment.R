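#' Vessel segmentation, skeletonization and centerline tracing
#'
#' The default segmentation path is classical: a multiscale Hessian-eigenvalue
#' vesselness filter tuned for dark tubular structures on a brighter
#' background (the appearance of vessels in the green channel), thresholded
#' and cleaned. A patch-based probabilistic predictor can be slotted in
#' instead via the `predictor` argument of [segment_vessels()] — any function
#' `patch -> probability patch`, applied over overlapping patches and stitched
#' by overlap averaging (the protocol used for patch-wise CNN segmenters:
#' 256 x 256 patches, overlap-averaged stitching, binarized at 0.5); training
#' such a model is out of scope here.
#'
#' @name segment
NULL

# ---- multiscale vesselness ---------------------------------------------------

# separable convolution with replicated edges via EBImage::filter2
conv_sep <- function(img, kr, kc) {
  k2 <- outer(kr, kc)
  EBImage::filter2(img, k2, boundary = "replicate")
}

gauss_kernels <- function(sigma, max_radius = Inf) {
  r <- max(1L, min(ceiling(3 * sigma), max_radius))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - sum(g2) / length(g2)  # keep zero-sum under truncation
  list(g = g, g1 = g1, g2 = g2)
}

#' Multiscale vesselness enhancement for dark tubular structures
#'
#' Frangi-type filter: at each scale s the image is convolved with Gaussian
#' second-derivative kernels, the Hessian eigenvalues (|l1| <= |l2|,
#' s^2-normalized) are formed per pixel, and the response combines the
#' blobness ratio `Rb = l1/l2` and the structure norm `S = sqrt(l1^2+l2^2)`:
#' `V = exp(-Rb^2/(2 beta^2)) * (1 - exp(-S^2/(2 c^2)))` where `l2 > 0`
#' (the polarity of a dark ridge on a bright background) and 0 elsewhere.
#' `c` is half the maximum `S` at that scale. The per-pixel maximum over
#' scales is restricted to pixels darker than their large-scale local mean by
#' 0.4 local standard deviations (the dark-polarity gate: tube responses
#' spill a halo around thin vessels at coarse scales, and a vessel pixel is
#' by definition substantially darker than its surroundings) and rescaled to
#' `[0, 1]`; a structureless (constant) input maps to all zeros.
#'
#' @param frame_green H x W matrix (green channel).
#' @param scales_px Gaussian scales in px; pick ~ half the expected vessel
#'   radius range, e.g. `c(2, 4, 8)` for vessels of 5-60 px width.
#' @param beta blobness sensitivity (default 0.5).
#' @return H x W vesselness image in `[0, 1]`.
#' @export
enhance_vessels <- function(frame_green, scales_px = c(2, 4, 8), beta = 0.5) {
  if (length(scales_px) == 0L || any(scales_px <= 0))
    stop_mf("scales_px must be non-empty and positive")
  img <- as.matrix(frame_green)
  out <- matrix(0, nrow(img), ncol(img))
  # kernels may not exceed the image (truncated support for very large scales)
  max_r <- (min(dim(img)) - 1L) %/% 2L
  for (s in scales_px) {
    k <- gauss_kernels(s, max_r)
    hyy <- s^2 * conv_sep(img, k$g2, k$g)
    hxx <- s^2 * conv_sep(img, k$g, k$g2)
    hxy <- s^2 * conv_sep(img, k$g1, k$g1)
    # eigenvalues of [[hyy, hxy], [hxy, hxx]]
    tr <- hyy + hxx
    dd <- sqrt(pmax((hyy - hxx)^2 + 4 * hxy^2, 0))
    e1 <- (tr + dd) / 2
    e2 <- (tr - dd) / 2
    swap <- abs(e1) > abs(e2)      # ensure |l1| <= |l2|
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    cmax <- sqrt(max(S2))
    if (cmax == 0) next
    c2 <- (cmax / 2)^2
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[l2 <= 0] <- 0                # dark vessels only
    out <- pmax(out, v)
  }
  # dark-polarity gate against coarse-scale halos: keep only pixels darker
  # than their large-scale local mean by a margin of 0.4 local standard
  # deviations (a vessel pixel is substantially darker than its
  # surroundings; mildly dark background texture is not)
  sg <- 1.5 * max(scales_px)
  kg <- gauss_kernels(sg, max_r)$g
  local_mean <- conv_sep(img, kg, kg)
  local_sd <- sqrt(pmax(conv_sep(img^2, kg, kg) - local_mean^2, 0))
  out[img >= local_mean - 0.4 * local_sd] <- 0
  mx <- max(out)
  if (mx > 0) out <- out / mx
  matrix(out, nrow(img), ncol(img))
}

#' Segment vessels from an enhancement image
#'
#' Thresholds the vesselness (or plugged-in predictor probability) image,
#' removes connected components smaller than `min_object_px` and fills holes
#' smaller than `min_object_px`.
#'
#' @param frame_green H x W green-channel matrix; used when `enhancement` is
#'   NULL or when a `predictor` is supplied.
#' @param enhancement optional precomputed enhancement image in `[0, 1]`.
#' @param threshold binarization threshold in (0, 1); 0.5 is the convention
#'   for probabilistic predictors, lower (~0.15) for vesselness responses.
#' @param min_object_px minimum component / hole size kept, px.
#' @param scales_px passed to [enhance_vessels()] when enhancement is computed
#'   here.
#' @param predictor optional function `patch matrix -> probability matrix`
#'   applied patchwise (patch 256, stride 128) and overlap-averaged.
#' @return binary H x W matrix (values 0/1).
#' @export
segment_vessels <- function(frame_green, enhancement = NULL, threshold = 0.15,
                            min_object_px = 50, scales_px = c(2, 4, 8),
                            predictor = NULL) {
  assert_scalar_num(threshold, "threshold", 0, 1)
  if (threshold <= 0) stop_mf("threshold must be in (0, 1)")
  if (is.null(enhancement)) {
    enhancement <- if (is.null(predictor)) {
      enhance_vessels(frame_green, scales_px)
    } else {
      predict_patchwise(frame_green, predictor)
    }
  }
  mask <- (enhancement >= threshold) * 1L
  clean_mask(mask, min_object_px)
}

# drop small components, fill small holes
clean_mask <- function(mask, min_object_px) {
  if (min_object_px <= 1 || !any(mask == 1L)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_object_px)
  if (length(small)) mask[lab %in% small] <- 0L
  # holes: background components not touching the border
  inv <- 1L - mask
  labb <- EBImage::bwlabel(inv)
  border_labels <- unique(c(labb[1, ], labb[nrow(labb), ],
                            labb[, 1], labb[, ncol(labb)]))
  bsz <- tabulate(labb[labb > 0])
  holes <- setdiff(which(bsz < min_object_px), border_labels)
  if (length(holes)) mask[labb %in% holes] <- 1L
  mask
}

# run a patch predictor over overlapping tiles and average overlaps
predict_patchwise <- function(img, predictor, patch_px = 256L,
                              stride_px = 128L) {
  patch_px <- min(patch_px, nrow(img), ncol(img))
  stride_px <- min(stride_px, patch_px)
  patches <- extract_patches(img, patch_px, stride_px)
  pred <- lapply(patches, function(p)
    list(patch = predictor(p$patch), origin = p$origin))
  stitch_patches(pred, dim(img))
}

# ---- patch extraction / stitching -------------------------------------------

#' Extract overlapping patches covering an image
#'
#' Patch origins advance by `stride_px`; the final patch in each dimension is
#' anchored to the image border, so every pixel is covered at least once.
#'
#' @param image H x W matrix.
#' @param patch_px square patch side (<= min(H, W)).
#' @param stride_px step between patch origins (<= patch_px).
#' @return list of `list(patch, origin)` with 0-based `(y, x)` origins.
#' @export
extract_patches <- function(image, patch_px, stride_px) {
  h <- nrow(image); w <- ncol(image)
  patch_px <- as.integer(patch_px); stride_px <- as.integer(stride_px)
  if (patch_px > min(h, w)) stop_mf("patch_px exceeds image size")
  if (stride_px > patch_px) stop_mf("stride_px must be <= patch_px")
  if (stride_px < 1L) stop_mf("stride_px must be >= 1")
  origins_1d <- function(dim) unique(c(seq(0L, dim - patch_px, by = stride_px),
                                       dim - patch_px))
  oy <- origins_1d(h); ox <- origins_1d(w)
  out <- list()
  for (y in oy) for (x in ox)
    out[[length(out) + 1L]] <- list(
      patch = image[(y + 1L):(y + patch_px), (x + 1L):(x + patch_px),
                    drop = FALSE],
      origin = c(y, x))
  out
}

#' Stitch patches back into an image by overlap averaging
#'
#' Each output pixel is the arithmetic mean of every patch value covering it;
#' cutting patches from an image and stitching them back is the exact
#' identity.
#'
#' @param patches list of `list(patch, origin)` as from [extract_patches()].
#' @param out_shape `c(H, W)` of the output.
#' @return H x W matrix.
#' @export
stitch_patches <- function(patches, out_shape) {
  acc <- matrix(0, out_shape[1], out_shape[2])
  cnt <- matrix(0, out_shape[1], out_shape[2])
  for (p in patches) {
    ph <- nrow(p$patch); pw <- ncol(p$patch)
    ry <- (p$origin[1] + 1L):(p$origin[1] + ph)
    rx <- (p$origin[2] + 1L):(p$origin[2] + pw)
    if (max(ry) > out_shape[1] || max(rx) > out_shape[2] || min(ry) < 1L ||
        min(rx) < 1L)
      stop_mf("patch at (%d, %d) exits the output", p$origin[1], p$origin[2])
    acc[ry, rx] <- acc[ry, rx] + p$patch
    cnt[ry, rx] <- cnt[ry, rx] + 1
  }
  if (any(cnt == 0)) stop_mf("stitch error: uncovered pixel(s)")
  acc / cnt
}

#' Confusion-matrix metrics for a predicted vessel mask
#'
#' @param pred,truth binary matrices of identical shape (1 = vessel).
#' @return list with `accuracy = (TP+TN)/total`, `recall = TP/(TP+FN)`,
#'   `specificity = TN/(TN+FP)`; a zero denominator yields `NA`, never 0.
#' @export
evaluate_segmentation <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop_mf("mask shape mismatch")
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t); tn <- sum(!p & !t)
  fp <- sum(p & !t); fn <- sum(!p & t)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = ratio(tp + tn, tp + tn + fp + fn),
       recall = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp))
}

# ---- thinning ----------------------------------------------------------------

# 8-neighbour maps by shifting with zero padding
nbr_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Thin a binary mask to a 1-pixel skeleton
#'
#' Zhang-Suen morphological thinning: iterative two-subiteration deletion of
#' boundary pixels that preserves the connectivity (homotopy) of every
#' component, yielding an 8-connected, 1-px-wide skeleton. Idempotent: the
#' skeleton of a skeleton is itself.
#'
#' @param mask binary H x W matrix.
#' @return binary H x W skeleton matrix (subset of `mask`).
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- nbr_shift(m, -1,  0); p3 <- nbr_shift(m, -1,  1)
      p4 <- nbr_shift(m,  0,  1); p5 <- nbr_shift(m,  1,  1)
      p6 <- nbr_shift(m,  1,  0); p7 <- nbr_shift(m,  1, -1)
      p8 <- nbr_shift(m,  0, -1); p9 <- nbr_shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1L & b >= 2 & b <= 6 & a == 1
      if (sub == 1) cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else          cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# 8-connected component labelling for sparse skeleton images (bwlabel is
# 4-connected, which would split diagonal chain steps)
label8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  px <- which(m == 1L)
  for (p in px) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      r <- (q - 1L) %% h + 1L; cc <- (q - 1L) %/% h + 1L
      for (dy in -1:1) for (dx in -1:1) {
        ny <- r + dy; nx2 <- cc + dx
        if (ny < 1L || nx2 < 1L || ny > h || nx2 > w) next
        if (m[ny, nx2] == 1L && lab[ny, nx2] == 0L) {
          lab[ny, nx2] <- nxt
          queue <- c(queue, (nx2 - 1L) * h + ny)
        }
      }
    }
  }
  lab
}

# degree of each skeleton pixel (number of 8-neighbours on the skeleton)
skeleton_degree <- function(sk) {
  deg <- matrix(0L, nrow(sk), ncol(sk))
  for (dy in -1:1) for (dx in -1:1)
    if (dy != 0 || dx != 0) deg <- deg + nbr_shift(sk, dy, dx)
  deg * sk
}

# crossing number: connected groups of 1s in the 8-neighbour ring. On a thinned
# skeleton a staircase pixel can have raw degree 3-4 because consecutive ring
# neighbours touch; the crossing number is 1 at a line end, 2 on a simple path
# and >= 3 only at true branches.
skeleton_xnum <- function(sk) {
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  p <- lapply(ring, function(d) nbr_shift(sk, d[1], d[2]))
  a <- matrix(0L, nrow(sk), ncol(sk))
  for (i in 1:8) {
    j <- if (i == 8) 1L else i + 1L
    a <- a + (p[[i]] == 0L & p[[j]] == 1L)
  }
  a * sk
}

#' Trace a centerline from a skeleton endpoint
#'
#' Ordered 8-connected walk starting at a degree-1 skeleton pixel, stopping at
#' the next endpoint or branch point (degree > 2). Cycles are rejected.
#'
#' @param skeleton binary skeleton matrix (from [skeletonize()]).
#' @param endpoint `c(y, x)` 0-based coordinates of a degree-1 skeleton pixel.
#' @param smooth smooth the traced points (moving average, window 5). A raw
#'   pixel walk is a staircase whose arc length overstates the geometric path
#'   length (up to sqrt(2)x), which would bias every arc-length-calibrated
#'   measurement — velocity most of all; smoothing restores the geometric
#'   length. Set FALSE to keep the raw pixel chain.
#' @return a [centerline()].
#' @export
trace_centerline <- function(skeleton, endpoint, smooth = TRUE) {
  sk <- matrix(as.integer(skeleton != 0), nrow(skeleton), ncol(skeleton))
  deg <- skeleton_degree(sk)
  y <- as.integer(endpoint[1]); x <- as.integer(endpoint[2])
  if (y < 0 || x < 0 || y >= nrow(sk) || x >= ncol(sk) ||
      sk[y + 1, x + 1] != 1L)
    stop_mf("endpoint (%d, %d) is not a skeleton pixel", y, x)
  if (deg[y + 1, x + 1] != 1L)
    stop_mf("endpoint must have degree 1 (got %d)", deg[y + 1, x + 1])
  pts <- walk_chain(sk, c(y, x))
  if (smooth && nrow(pts) >= 5L) pts <- dedupe_points(smooth_points(pts, 5L))
  centerline(pts)
}

# drop consecutive (near-)duplicate points a smoothed zigzag can produce
dedupe_points <- function(pts) {
  if (nrow(pts) < 2L) return(pts)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
  pts[keep, , drop = FALSE]
}

# greedy ordered walk from a chain end, stopping at a branch (crossing
# number >= 3) or when no unvisited neighbour remains (a cycle cannot be
# entered from an endpoint; loop components are rejected upstream)
walk_chain <- function(sk, start) {
  xn <- skeleton_xnum(sk)
  visited <- matrix(FALSE, nrow(sk), ncol(sk))
  path <- list(start)
  visited[start[1] + 1, start[2] + 1] <- TRUE
  repeat {
    cur <- path[[length(path)]]
    if (length(path) > 1L && xn[cur[1] + 1, cur[2] + 1] >= 3L) break
    nbrs <- list()
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ny <- cur[1] + dy; nx <- cur[2] + dx
      if (ny < 0 || nx < 0 || ny >= nrow(sk) || nx >= ncol(sk)) next
      if (sk[ny + 1, nx + 1] == 1L && !visited[ny + 1, nx + 1])
        nbrs[[length(nbrs) + 1L]] <- c(ny, nx)
    }
    if (length(nbrs) == 0L) break
    # prefer 4-connected steps so the walk does not cut corners
    d4 <- vapply(nbrs, function(p) sum(abs(p - cur)), 0)
    nxt <- nbrs[[order(d4)[1]]]
    visited[nxt[1] + 1, nxt[2] + 1] <- TRUE
    path[[length(path) + 1L]] <- nxt
  }
  do.call(rbind, path)
}

#' Prune short spur branches from a skeleton
#'
#' Thinning an irregular mask leaves short side twigs at boundary dents. A
#' spur is an endpoint chain that meets a branch point within `prune_px`
#' steps; such chains are deleted (the branch pixel stays). Long open lines
#' are never touched. Repeats until stable.
#'
#' @param skeleton binary skeleton matrix.
#' @param prune_px maximum spur length removed.
#' @return pruned binary skeleton matrix.
#' @export
prune_skeleton <- function(skeleton, prune_px = 8) {
  sk <- matrix(as.integer(skeleton != 0), nrow(skeleton), ncol(skeleton))
  repeat {
    xn <- skeleton_xnum(sk)
    ends <- which(xn == 1L & sk == 1L, arr.ind = TRUE)
    removed <- FALSE
    for (i in seq_len(nrow(ends))) {
      start <- c(ends[i, 1] - 1L, ends[i, 2] - 1L)
      if (sk[start[1] + 1, start[2] + 1] != 1L) next
      pts <- walk_chain(sk, start)
      n <- nrow(pts)
      last <- pts[n, ]
      at_branch <- skeleton_xnum(sk)[last[1] + 1, last[2] + 1] >= 3L
      if (at_branch && n - 1L <= prune_px) {
        sk[pts[-n, , drop = FALSE] + 1L] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

#' Extract all branch-free centerlines from a skeleton
#'
#' Spur branches up to `prune_px` are pruned first, true branch points
#' (crossing number >= 3) are removed, and each remaining 8-connected chain
#' is traced from one of its ends. Chains shorter than `min_length_px` and
#' loop components are dropped.
#'
#' @param skeleton binary skeleton matrix.
#' @param min_length_px minimum chain length in pixels.
#' @param prune_px spur-pruning length (see [prune_skeleton()]).
#' @return list of [centerline()] objects.
#' @export
centerline_paths <- function(skeleton, min_length_px = 20, prune_px = 8) {
  sk <- prune_skeleton(skeleton, prune_px)
  xn <- skeleton_xnum(sk)
  # clear branch points together with their 8-neighbourhood: arms meeting at
  # a junction stay diagonally adjacent if only the junction pixel goes
  branch <- (xn >= 3L) * 1L
  bd <- branch
  for (dy in -1:1) for (dx in -1:1)
    if (dy != 0 || dx != 0) bd <- bd | nbr_shift(branch, dy, dx)
  sk2 <- sk; sk2[bd == 1L] <- 0L
  lab <- label8(sk2)
  out <- list()
  for (l in seq_len(max(lab))) {
    comp <- which(lab == l, arr.ind = TRUE)
    if (nrow(comp) < max(2L, min_length_px)) next
    cm <- matrix(0L, nrow(sk), ncol(sk))
    cm[comp] <- 1L
    cxn <- skeleton_xnum(cm)
    ends <- which(cxn == 1L & cm == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) next  # loop component
    ep <- c(ends[1, 1] - 1L, ends[1, 2] - 1L)
    pts <- walk_chain(cm, ep)
    if (nrow(pts) >= 5L) pts <- dedupe_points(smooth_points(pts, 5L))
    path <- tryCatch(centerline(pts), error = function(e) NULL)
    if (!is.null(path) && length(path) >= min_length_px)
      out[[length(out) + 1L]] <- path
  }
  out
}
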