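#' Calibrated image sequences
#'
#' An `image_sequence` is the container the whole pipeline consumes: a stack of
#' frames together with the physical calibration (pixel size in micrometres and
#' the frame interval in seconds) that converts pixel/frame measurements into
#' micrometres per second. Calibration is always supplied explicitly; there is
#' no silent default, because every downstream velocity and diameter is scaled
#' by it.
#'
#' Frames are stored as an `H x W x C x T` array of intensities in `[0, 1]`
#' (`C` is 1 for grayscale, 3 for RGB). Pixel coordinates are 0-based
#' `(row, col) = (y, x)`.
#'
#' @param frames numeric array `H x W x C x T` (or `H x W x T` / `H x W`,
#'   which are promoted), intensities in `[0, 1]`.
#' @param pixel_size_um physical size of one pixel, micrometres (> 0).
#' @param frame_interval_s time between consecutive frames, seconds (> 0).
#' @param bit_depth integer, 8 or 16; the container depth used when frames are
#'   written to disk. 14-bit camera data lives in 16-bit containers, used as-is.
#' @return an object of class `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_size_um, frame_interval_s,
                           bit_depth = 8L) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L, 1L)
  if (length(dim(frames)) == 3L) {
    d <- dim(frames)
    if (d[3] %in% c(1L, 3L)) dim(frames) <- c(d, 1L)  # single frame H x W x C
    else dim(frames) <- c(d[1], d[2], 1L, d[3])       # gray stack H x W x T
  }
  d <- dim(frames)
  if (length(d) != 4L || !(d[3] %in% c(1L, 3L)))
    stop_mf("frames must be H x W x C x T with C in {1, 3}")
  if (d[4] < 1L) stop_mf("sequence must have at least one frame")
  assert_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", 0, strict_lower = TRUE)
  if (!bit_depth %in% c(8L, 16L)) stop_mf("bit_depth must be 8 or 16")
  structure(list(frames = frames,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 bit_depth = as.integer(bit_depth)),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_sequence: %d frame(s), %d x %d px, %d channel(s), %d-bit\n",
    d[4], d[1], d[2], d[3], x$bit_depth))
  cat(sprintf("  pixel size %.4g um, frame interval %.4g s (%.4g fps)\n",
              x$pixel_size_um, x$frame_interval_s, 1 / x$frame_interval_s))
  invisible(x)
}

#' @export
dim.image_sequence <- function(x) dim(x$frames)

#' Number of frames in a sequence
#' @param seq an `image_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[4]

#' Extract one frame
#' @param seq an `image_sequence`.
#' @param t frame index, 1-based.
#' @return `H x W x C` array.
#' @export
get_frame <- function(seq, t) seq$frames[, , , t, drop = FALSE][, , , 1]

#' Extract the green channel of one frame
#'
#' Vessel contrast is strongest in the green channel (haemoglobin absorbs green
#' light), so segmentation, registration, RPCA and diameter profiles all read
#' this channel. Grayscale sequences return their single channel.
#'
#' @param seq an `image_sequence`.
#' @param t frame index, 1-based.
#' @return `H x W` matrix.
#' @export
green_frame <- function(seq, t) {
  ch <- if (dim(seq$frames)[3] == 3L) 2L else 1L
  matrix(seq$frames[, , ch, t], dim(seq$frames)[1], dim(seq$frames)[2])
}

#' Read a calibrated image sequence
#'
#' Accepts either a multi-page TIFF stack or a directory of numbered PNG/TIFF
#' frames (ordered lexicographically). Calibration must be supplied; a missing
#' pixel size or frame interval is an error, never a default.
#'
#' @param path TIFF file or directory of frames.
#' @param pixel_size_um,frame_interval_s calibration (required).
#' @param bit_depth container depth for later writes; default 8.
#' @return an `image_sequence`; intensities as stored on disk (in `[0, 1]`).
#' @export
read_sequence <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                          bit_depth = 8L) {
  if (is.null(pixel_size_um) || is.null(frame_interval_s))
    stop_mf("calibration (pixel_size_um, frame_interval_s) is required")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop_mf("no PNG/TIFF frames found in '%s'", path)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    })
  } else if (file.exists(path)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
  } else stop_mf("path '%s' does not exist", path)
  shapes <- vapply(frames, function(f) paste(dim(f) %||% length(f),
                                             collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_mf("mixed frame shapes in '%s': %s", path,
            paste(unique(shapes), collapse = ", "))
  frames <- lapply(frames, function(f) {
    if (is.matrix(f)) dim(f) <- c(dim(f), 1L)
    f
  })
  d <- dim(frames[[1]])
  if (d[3] == 4L) { frames <- lapply(frames, function(f) f[, , 1:3]); d[3] <- 3L }
  arr <- array(unlist(frames), dim = c(d, length(frames)))
  image_sequence(arr, pixel_size_um, frame_interval_s, bit_depth)
}

#' Write an image sequence
#'
#' Writes a multi-page TIFF (`format = "tiff"`) or a directory of numbered PNG
#' frames. Intensities are quantized to the sequence's `bit_depth`; sequences
#' produced by [render_scene()] are already on that grid, so the write/read
#' round trip is bit-exact.
#'
#' @param seq an `image_sequence`.
#' @param path output file (tiff) or directory (png).
#' @param format "tiff" or "png".
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  n <- n_frames(seq)
  drop_gray <- function(f) if (dim(f)[3] == 1L) f[, , 1] else f
  if (format == "tiff") {
    frames <- lapply(seq_len(n), function(t) drop_gray(get_frame3(seq, t)))
    tiff::writeTIFF(frames, path, bits.per.sample = seq$bit_depth)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    fmt <- paste0("frame_%0", max(4L, nchar(n)), "d.png")
    for (t in seq_len(n))
      png::writePNG(drop_gray(get_frame3(seq, t)),
                    file.path(path, sprintf(fmt, t - 1L)))
  }
  invisible(path)
}

# frame as H x W x C array (keeps C dim)
get_frame3 <- function(seq, t) {
  d <- dim(seq$frames)
  array(seq$frames[, , , t], dim = d[1:3])
}

#' Write result records with a provenance sidecar
#'
#' Records (one per measured quantity per vessel per timepoint) go to CSV with
#' a stable column order; the run configuration is echoed to a JSON sidecar
#' (`<path>.json`) so the run can be reproduced.
#'
#' @param records data.frame with columns `timepoint_h`, `vessel_id`,
#'   `quantity`, `value`, `units` (an empty data.frame yields a header-only
#'   CSV).
#' @param path output CSV path.
#' @param config optional list echoed into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, config = NULL) {
  cols <- c("timepoint_h", "vessel_id", "quantity", "value", "units")
  if (nrow(records) == 0L) {
    records <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  } else {
    missing <- setdiff(cols, names(records))
    if (length(missing))
      stop_mf("records missing column(s): %s", paste(missing, collapse = ", "))
    records <- records[cols]
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config = config %||% list(), n_records = nrow(records)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- run configuration -------------------------------------------------------

config_defaults <- function() list(
  pixel_size_um      = NULL,    # required, no silent default
  frame_interval_s   = NULL,    # required
  search_radius_px   = 5,       # registration search radius
  template_box       = NULL,    # c(x, y, w, h) 0-based; NULL = full frame
  vesselness_scales  = c(2, 4, 8),
  seg_threshold      = 0.15,
  min_object_px      = 50,
  rpca_lambda        = NULL,    # NULL = 1/sqrt(max(m, n))
  rpca_tol           = 1e-7,
  rpca_max_iter      = 500,
  rpca_window        = 150,     # frames per decomposition
  kymo_frames        = 150,
  min_centerline_px  = 40,
  diam_interval_px   = 10,
  diam_half_length_px = 40,
  velocity_class_only = TRUE,   # velocity only for 20-100 um vessels
  alpha              = 0.1
)

#' Build and validate a run configuration
#'
#' Every pipeline parameter in one validated list. Unknown keys are rejected
#' (a typo never silently falls back to a default) and every numeric field is
#' range-checked, so a configuration either validates completely or fails with
#' a named error.
#'
#' @param ... named overrides of the defaults (see Details).
#' @details Key fields: `pixel_size_um` (um/px) and `frame_interval_s` (s) are
#'   required; `search_radius_px` bounds registration shifts;
#'   `vesselness_scales` (px) and `seg_threshold` control segmentation;
#'   `rpca_lambda` (default `1/sqrt(max(m, n))`), `rpca_tol`, `rpca_window`
#'   control the low-rank/sparse decomposition; `kymo_frames` is the
#'   spatiotemporal window (default 150 frames); `alpha` the significance
#'   level (default 0.1).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- config_defaults()
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == "")))
    stop_mf("all config entries must be named")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop_mf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  if (is.null(cfg$pixel_size_um))
    stop_mf("config error: 'pixel_size_um' is required")
  if (is.null(cfg$frame_interval_s))
    stop_mf("config error: 'frame_interval_s' is required")
  assert_scalar_num(cfg$pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$frame_interval_s, "frame_interval_s", 0,
                    strict_lower = TRUE)
  assert_scalar_num(cfg$search_radius_px, "search_radius_px", 0)
  assert_scalar_num(cfg$seg_threshold, "seg_threshold", 0, 1)
  assert_scalar_num(cfg$min_object_px, "min_object_px", 0)
  assert_scalar_num(cfg$rpca_tol, "rpca_tol", 0, strict_lower = TRUE)
  assert_scalar_num(cfg$rpca_max_iter, "rpca_max_iter", 1)
  assert_scalar_num(cfg$rpca_window, "rpca_window", 2)
  assert_scalar_num(cfg$kymo_frames, "kymo_frames", 8)
  assert_scalar_num(cfg$diam_interval_px, "diam_interval_px", 1)
  assert_scalar_num(cfg$diam_half_length_px, "diam_half_length_px", 2)
  assert_scalar_num(cfg$alpha, "alpha", 0, 1)
  if (!is.numeric(cfg$vesselness_scales) || any(cfg$vesselness_scales <= 0))
    stop_mf("vesselness_scales must be positive")
  if (!is.null(cfg$rpca_lambda))
    assert_scalar_num(cfg$rpca_lambda, "rpca_lambda", 0, strict_lower = TRUE)
  if (!is.null(cfg$template_box) && length(cfg$template_box) != 4L)
    stop_mf("template_box must be c(x, y, w, h)")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] fields.
#' @return validated `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
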