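# Internal helpers shared across modules. All public pixel coordinates are
# 0-based (row, col) = (y, x); subpixel positions are real-valued in that frame.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mf("'%s' must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stop_mf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_mf("'%s' must be >= %g", name, lower)
  if (x > upper)
    stop_mf("'%s' must be <= %g", name, upper)
  invisible(x)
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bilinear interpolation of matrix `m` at 0-based subpixel (y, x) vectors.
# Coordinates are clamped to the image domain.
bilinear_sample <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  y <- pmin(pmax(y, 0), h - 1)
  x <- pmin(pmax(x, 0), w - 1)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- y - y0; fx <- x - x0
  i00 <- m[cbind(y0 + 1, x0 + 1)]
  i01 <- m[cbind(y0 + 1, x1 + 1)]
  i10 <- m[cbind(y1 + 1, x0 + 1)]
  i11 <- m[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Integer translation with edge replication: content at (y, x) moves to
# (y + dy, x + dx). Works on a matrix.
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  src_r <- pmin(pmax(seq_len(h) - dy, 1L), h)
  src_c <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[src_r, src_c, drop = FALSE]
}

# Per-pixel temporal quantile across the frames of a T-long list of matrices
# or an H x W x T array; returns an H x W matrix. A low quantile (default
# 0.1) gives a "background" frame immune to transient bright particles.
quantile_image <- function(frames, prob = 0.1) {
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  d <- dim(frames)
  m <- matrix(frames, nrow = d[1] * d[2], ncol = d[3])
  matrix(apply(m, 1L, stats::quantile, probs = prob, names = FALSE),
         d[1], d[2])
}
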