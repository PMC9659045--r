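#' Robust PCA: low-rank + sparse video decomposition
#'
#' A registered microcirculation video, unrolled so that each frame is one
#' column, is approximately the sum of a low-rank matrix (the static tissue
#' and vessel background, nearly identical across frames) and a sparse matrix
#' (the few bright pixels of moving red blood cells plus residual motion).
#' Principal component pursuit recovers the two by solving
#'
#'   minimize  ||L||_* + lambda ||S||_1   subject to  D = L + S
#'
#' via inexact augmented-Lagrangian iterations: singular-value thresholding
#' for L, entrywise soft thresholding for S. The sparse component is the RBC
#' signal that the kymograph velocimetry stage consumes.
#'
#' @name rpca
NULL

#' Unroll a video into a matrix, one column per frame
#'
#' @param seq an [image_sequence()] (typically a registered sequence).
#' @param channel "green" (default), "red", "blue", or a channel index.
#' @param crop_box optional `c(x, y, w, h)` (0-based) region to unroll.
#' @return `video_matrix`: list with `D` (pixels x frames, column-major pixel
#'   order) and reshape metadata; [matrix_to_video()] inverts it exactly.
#' @export
video_to_matrix <- function(seq, channel = "green", crop_box = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$frames)
  ch <- if (is.numeric(channel)) as.integer(channel)
        else switch(channel, red = 1L, green = 2L, blue = 3L,
                    stop_mf("unknown channel '%s'", channel))
  if (d[3] == 1L) ch <- 1L
  if (is.null(crop_box)) crop_box <- c(0L, 0L, d[2], d[1])
  x0 <- crop_box[1]; y0 <- crop_box[2]; cw <- crop_box[3]; chh <- crop_box[4]
  if (x0 < 0 || y0 < 0 || x0 + cw > d[2] || y0 + chh > d[1])
    stop_mf("crop_box outside frame")
  n <- d[4]
  D <- matrix(0, chh * cw, n)
  for (t in seq_len(n))
    D[, t] <- as.vector(seq$frames[(y0 + 1):(y0 + chh),
                                   (x0 + 1):(x0 + cw), ch, t])
  structure(list(D = D, h = chh, w = cw, crop_box = crop_box, channel = ch,
                 pixel_size_um = seq$pixel_size_um,
                 frame_interval_s = seq$frame_interval_s),
            class = "video_matrix")
}

#' Reshape a pixels-x-frames matrix back into a grayscale sequence
#' @param M matrix with one column per frame.
#' @param vm the `video_matrix` carrying the reshape metadata.
#' @return an [image_sequence()] (grayscale).
#' @export
matrix_to_video <- function(M, vm) {
  stopifnot(inherits(vm, "video_matrix"))
  n <- ncol(M)
  arr <- array(0, dim = c(vm$h, vm$w, 1L, n))
  for (t in seq_len(n)) arr[, , 1L, t] <- matrix(M[, t], vm$h, vm$w)
  image_sequence(pmin(pmax(arr, 0), 1), vm$pixel_size_um, vm$frame_interval_s)
}

soft_threshold <- function(x, tau) sign(x) * pmax(abs(x) - tau, 0)

# economy SVD: for strongly rectangular matrices the eigendecomposition of
# the small Gram matrix is several times faster than LAPACK dgesdd on the
# full matrix, at equal accuracy for the singular values that matter here
# (those above the shrinkage threshold)
svd_econ <- function(X) {
  m <- nrow(X); n <- ncol(X)
  if (m >= 2L * n) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    pos <- d > max(d[1], 1e-300) * 1e-9
    V <- e$vectors
    U <- X %*% V[, pos, drop = FALSE] %*% diag(1 / d[pos], sum(pos))
    list(d = d, u = U, v = V[, pos, drop = FALSE], rank = sum(pos))
  } else if (n >= 2L * m) {
    s <- svd_econ(t(X))
    list(d = s$d, u = s$v, v = s$u, rank = s$rank)
  } else {
    s <- svd(X)
    list(d = s$d, u = s$u, v = s$v, rank = length(s$d))
  }
}

#' Principal component pursuit by inexact augmented Lagrangian
#'
#' Solves `min ||L||_* + lambda ||S||_1 s.t. D = L + S`. Each iteration
#' soft-thresholds `D - L + Y/mu` to update S, singular-value-thresholds
#' `D - S + Y/mu` at `1/mu` to update L, and takes a dual ascent step on Y;
#' `mu` grows geometrically (factor 1.5). Deterministic for fixed inputs.
#'
#' @param D numeric matrix or a `video_matrix`; must be finite.
#' @param lambda sparsity weight; default `1/sqrt(max(m, n))`, the standard
#'   choice under which exact recovery of incoherent low-rank + sparse
#'   decompositions is guaranteed.
#' @param tol convergence tolerance on the relative residual
#'   `||D - L - S||_F / ||D||_F` (default 1e-7).
#' @param max_iter iteration cap (default 500).
#' @return object of class `rpca`: `L`, `S`, `lambda`, `iterations`,
#'   `converged`, `residual`, `residual_history`, plus the reshape metadata
#'   when the input was a `video_matrix`.
#' @export
rpca_decompose <- function(D, lambda = NULL, tol = 1e-7, max_iter = 500) {
  vm <- NULL
  if (inherits(D, "video_matrix")) { vm <- D; D <- vm$D }
  if (!is.matrix(D) || !all(is.finite(D)))
    stop_mf("D must be a finite numeric matrix")
  assert_scalar_num(tol, "tol", 0, strict_lower = TRUE)
  m <- nrow(D); n <- ncol(D)
  lambda <- lambda %||% (1 / sqrt(max(m, n)))
  assert_scalar_num(lambda, "lambda", 0, strict_lower = TRUE)

  normD <- sqrt(sum(D^2))
  if (normD == 0)
    return(structure(list(L = D, S = D, lambda = lambda, iterations = 0L,
                          converged = TRUE, residual = 0,
                          residual_history = numeric(0), vm = vm),
                     class = "rpca"))
  # standard inexact-ALM initialization
  norm2 <- svd(D, nu = 0, nv = 0)$d[1]
  normInf <- max(abs(D)) / lambda
  Y <- D / max(norm2, normInf)
  mu <- 1.25 / norm2
  mu_max <- mu * 1e7
  rho <- 1.5
  L <- matrix(0, m, n); S <- matrix(0, m, n)
  hist <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S <- soft_threshold(D - L + Y / mu, lambda / mu)
    sv <- svd_econ(D - S + Y / mu)
    keep <- which(sv$d > 1 / mu)
    keep <- keep[keep <= min(ncol(sv$u), ncol(sv$v))]
    L <- if (length(keep)) {
      dk <- sv$d[keep] - 1 / mu
      sv$u[, keep, drop = FALSE] %*% (dk * t(sv$v[, keep, drop = FALSE]))
    } else matrix(0, m, n)
    Z <- D - L - S
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_max)
    res <- sqrt(sum(Z^2)) / normD
    hist <- c(hist, res)
    if (res < tol) { converged <- TRUE; break }
  }
  structure(list(L = L, S = S, lambda = lambda, iterations = it,
                 converged = converged, residual = hist[length(hist)],
                 residual_history = hist, vm = vm),
            class = "rpca")
}

#' @export
print.rpca <- function(x, ...) {
  cat(sprintf(
    "rpca: %d x %d, lambda %.4g, %d iteration(s), %sconverged (residual %.3g)\n",
    nrow(x$L), ncol(x$L), x$lambda, x$iterations,
    if (x$converged) "" else "NOT ", x$residual))
  rnk <- sum(svd(x$L, nu = 0, nv = 0)$d > 1e-8 * max(1e-12, max(abs(x$L))))
  cat(sprintf("  rank(L) ~ %d, nnz(S) %.1f%%\n", rnk,
              100 * mean(abs(x$S) > 1e-12)))
  invisible(x)
}

#' Sparse component as a normalized grayscale video
#'
#' The magnitude of the sparse component (both polarities count as RBC
#' signal) reshaped to frames and rescaled to `[0, 1]` by a fixed robust
#' rule: division by the 99.5th percentile of |S|, then clipping.
#'
#' @param result an `rpca` object produced from a `video_matrix`.
#' @param allow_partial accept a non-converged decomposition.
#' @return an [image_sequence()] (grayscale) — the "sparse video" the
#'   kymograph stage samples.
#' @export
sparse_video <- function(result, allow_partial = FALSE) {
  stopifnot(inherits(result, "rpca"))
  if (is.null(result$vm))
    stop_mf("decomposition was not built from a video_matrix")
  if (!result$converged && !allow_partial)
    stop_mf("decomposition did not converge (set allow_partial = TRUE)")
  A <- abs(result$S)
  q <- stats::quantile(A, 0.995, names = FALSE)
  if (q > 0) A <- pmin(A / q, 1)
  matrix_to_video(A, result$vm)
}
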