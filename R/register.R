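#' Body-motion correction by template matching
#'
#' Whole-body motion of the animal translates the entire field of view; before
#' any vessel analysis every frame is registered to the first frame (the
#' target) by maximizing the normalized cross-correlation of a template region
#' over integer shifts within a search radius. Integer shifts keep intensities
#' unresampled — the downstream low-rank/sparse decomposition tolerates the
#' sub-pixel residual. Matching runs on the green channel, where vessel
#' contrast is strongest.
#'
#' Ties in the correlation score are broken by smallest shift magnitude, then
#' smallest dy, then smallest dx, so the result is deterministic.
#'
#' @param seq an [image_sequence()].
#' @param template_box optional `c(x, y, w, h)` (0-based) region used for
#'   matching; default the full frame.
#' @param search_radius_px maximum |dy|, |dx| searched (>= 0).
#' @return a `corrected_sequence`: the input sequence with translated frames
#'   (out-of-frame pixels filled by edge replication) plus `shifts`, an
#'   n x 2 matrix of applied (dy, dx) per frame (`shifts[1, ] = c(0, 0)`), and
#'   `clipped`, a logical flag per frame set when the correlation peak sat on
#'   the search boundary (true motion may exceed the radius).
#' @export
register_sequence <- function(seq, template_box = NULL, search_radius_px = 5) {
  stopifnot(inherits(seq, "image_sequence"))
  assert_scalar_num(search_radius_px, "search_radius_px", 0)
  r <- as.integer(search_radius_px)
  h <- dim(seq$frames)[1]; w <- dim(seq$frames)[2]; n <- n_frames(seq)

  if (is.null(template_box)) template_box <- c(0, 0, w, h)
  x0 <- as.integer(template_box[1]); y0 <- as.integer(template_box[2])
  bw <- as.integer(template_box[3]); bh <- as.integer(template_box[4])
  if (x0 < 0 || y0 < 0 || x0 + bw > w || y0 + bh > h || bw < 2 || bh < 2)
    stop_mf("template_box must lie inside the %d x %d frame", h, w)
  # shrink the box so that box +- radius stays in-frame (keeps the candidate
  # comparison windows fully valid without edge effects)
  yy <- (max(y0, r)):(min(y0 + bh, h - r) - 1L)
  xx <- (max(x0, r)):(min(x0 + bw, w - r) - 1L)
  if (length(yy) < 2L || length(xx) < 2L)
    stop_mf("template_box too small for search radius %d", r)

  target <- green_frame(seq, 1)
  tpl <- target[yy + 1L, xx + 1L]
  if (stats::sd(tpl) == 0) stop_mf("degenerate template: zero variance")
  tpl_v <- as.vector(tpl)

  cand <- expand.grid(dy = -r:r, dx = -r:r)
  ord <- order(cand$dy^2 + cand$dx^2, abs(cand$dy), abs(cand$dx))
  cand <- cand[ord, ]  # tie-break order: smallest magnitude, then dy, then dx

  shifts <- matrix(0L, n, 2)
  clipped <- logical(n)
  frames <- seq$frames
  for (t in seq_len(n)) {
    if (t == 1L) next
    g <- green_frame(seq, t)
    best <- -Inf; best_dy <- 0L; best_dx <- 0L
    for (k in seq_len(nrow(cand))) {
      dy <- cand$dy[k]; dx <- cand$dx[k]
      # shifted frame value at (y, x) is g[y - dy, x - dx]
      win <- g[yy - dy + 1L, xx - dx + 1L]
      sw <- stats::sd(win)
      score <- if (sw == 0) -Inf else
        stats::cor(tpl_v, as.vector(win))
      if (score > best + 1e-12) {
        best <- score; best_dy <- dy; best_dx <- dx
      }
    }
    shifts[t, ] <- c(best_dy, best_dx)
    clipped[t] <- (abs(best_dy) == r || abs(best_dx) == r) && r > 0
    if (best_dy != 0L || best_dx != 0L)
      for (ch in seq_len(dim(frames)[3]))
        frames[, , ch, t] <- shift_matrix(
          matrix(frames[, , ch, t], h, w), best_dy, best_dx)
  }
  out <- seq
  out$frames <- frames
  out$shifts <- shifts
  out$clipped <- clipped
  class(out) <- c("corrected_sequence", "image_sequence")
  out
}

#' @export
print.corrected_sequence <- function(x, ...) {
  NextMethod()
  mags <- sqrt(rowSums(x$shifts^2))
  cat(sprintf("  registered to frame 1: max |shift| %.1f px, %d clipped\n",
              max(mags), sum(x$clipped)))
  invisible(x)
}
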