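#' Run the full microcirculation analysis pipeline
#'
#' Executes the stages in their processing order: (1) registration of every
#' frame to the first, (2) vessel segmentation on the per-pixel median green
#' frame, (3) thinning and centerline tracing, (4) low-rank/sparse
#' decomposition of the registered green video, (5) per-vessel diameter
#' (FWHM) and, for vessels in the 20-100 um class, velocity from the
#' kymograph spectrum. Deterministic given the input and configuration: no
#' stage consumes a clock or unseeded random source.
#'
#' @param input an [image_sequence()] or a path readable by
#'   [read_sequence()].
#' @param config a [run_config()].
#' @param out_dir optional directory: intermediate artifacts (shift table,
#'   mask PNG, results CSV, report JSON) are written there.
#' @param centerlines optional list of [centerline()] objects; when supplied
#'   the segmentation stage is skipped and these paths are analysed instead
#'   (the workflow where vessels are selected externally).
#' @return a `pipeline_report`: per-stage status and timing, per-vessel
#'   `results` data.frame (`vessel_id`, `quantity`, `value`, `units`),
#'   `warnings`, config echo, and the intermediate objects (`corrected`,
#'   `mask`, `skeleton`, `centerlines`, `sparse`).
#' @export
run_pipeline <- function(input, config, out_dir = NULL, centerlines = NULL) {
  if (!inherits(config, "run_config"))
    stop_mf("config must be a run_config object")
  report <- list(stages = list(), warnings = character(0),
                 config = unclass(config),
                 version = as.character(utils::packageVersion("microflow")))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    report$stages[[name]] <<- list(status = "ok",
                                   seconds = proc.time()[["elapsed"]] - t0)
    val
  }
  fail <- function(name, e) {
    report$stages[[name]] <- list(status = "error", message = conditionMessage(e))
    stop_mf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  }

  seq <- if (inherits(input, "image_sequence")) input else
    t_stage("read", read_sequence(input, config$pixel_size_um,
                                  config$frame_interval_s))

  corrected <- tryCatch(
    t_stage("register",
            register_sequence(seq, config$template_box,
                              config$search_radius_px)),
    error = function(e) fail("register", e))
  if (any(corrected$clipped))
    report$warnings <- c(report$warnings, sprintf(
      "%d frame(s) hit the registration search radius", sum(corrected$clipped)))

  n <- n_frames(corrected)
  # static background frame: temporal 10th percentile of the green channel,
  # insensitive to passing bright cells (unlike mean or median under heavy
  # traffic); segmentation and diameter both read this frame
  med <- quantile_image(lapply(seq_len(n), function(t)
    green_frame(corrected, t)))

  if (is.null(centerlines)) {
    seg <- tryCatch(t_stage("segment", {
      enh <- enhance_vessels(med, config$vesselness_scales)
      segment_vessels(med, enhancement = enh,
                      threshold = config$seg_threshold,
                      min_object_px = config$min_object_px)
    }), error = function(e) fail("segment", e))
    sk <- tryCatch(t_stage("thin", skeletonize(seg)),
                   error = function(e) fail("thin", e))
    centerlines <- tryCatch(
      t_stage("trace", centerline_paths(sk, config$min_centerline_px)),
      error = function(e) fail("trace", e))
  } else {
    seg <- NULL; sk <- NULL
    report$stages$segment <- list(status = "skipped (external centerlines)")
  }
  if (length(centerlines) == 0L)
    stop_mf("pipeline stage 'trace' failed: no centerlines found")

  win <- min(config$rpca_window, n)
  sp <- tryCatch(t_stage("rpca", {
    vm <- video_to_matrix(corrected, channel = "green")
    vm$D <- vm$D[, seq_len(win), drop = FALSE]
    dec <- rpca_decompose(vm, lambda = config$rpca_lambda,
                          tol = config$rpca_tol,
                          max_iter = config$rpca_max_iter)
    sparse_video(dec, allow_partial = TRUE)
  }), error = function(e) fail("rpca", e))

  results <- list()
  for (i in seq_along(centerlines)) {
    path <- centerlines[[i]]
    vid <- sprintf("vessel_%02d", i)
    diam <- tryCatch(
      vessel_diameter(med, path, config$diam_interval_px,
                      config$diam_half_length_px, config$pixel_size_um),
      error = function(e) {
        report$warnings <<- c(report$warnings,
                              sprintf("%s: diameter failed (%s)", vid,
                                      conditionMessage(e)))
        NULL
      })
    if (is.null(diam)) next
    results[[length(results) + 1L]] <- data.frame(
      vessel_id = vid, quantity = "diameter", value = diam$fwhm_um,
      units = "um")
    results[[length(results) + 1L]] <- data.frame(
      vessel_id = vid, quantity = "vessel_class", value = NA_real_,
      units = diam$vessel_class)
    do_vel <- !config$velocity_class_only ||
      diam$vessel_class == "arteriole_vein"
    if (do_vel && arc_length(path) >= 8) {
      vel <- tryCatch(
        estimate_velocity(sp, path, t0 = 0,
                          n_frames = min(config$kymo_frames, win)),
        error = function(e) {
          report$warnings <<- c(report$warnings,
                                sprintf("%s: velocity failed (%s)", vid,
                                        conditionMessage(e)))
          NULL
        })
      if (!is.null(vel))
        results[[length(results) + 1L]] <- data.frame(
          vessel_id = vid, quantity = "velocity", value = vel$velocity_um_s,
          units = "um/s")
    }
  }
  report$results <- if (length(results)) do.call(rbind, results) else
    data.frame(vessel_id = character(0), quantity = character(0),
               value = numeric(0), units = character(0))
  report$corrected <- corrected
  report$mask <- seg
  report$skeleton <- sk
  report$centerlines <- centerlines
  report$sparse <- sp
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(data.frame(frame = seq_len(n) - 1L,
                                dy = corrected$shifts[, 1],
                                dx = corrected$shifts[, 2]),
                     file.path(out_dir, "shifts.csv"), row.names = FALSE)
    if (!is.null(seg))
      png::writePNG(matrix(as.numeric(seg), nrow(seg), ncol(seg)),
                    file.path(out_dir, "vessel_mask.png"))
    rec <- report$results
    rec$timepoint_h <- 0
    write_results(rec, file.path(out_dir, "results.csv"),
                  config = unclass(config))
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_list <- function(report) {
  list(version = report$version,
       stages = report$stages,
       warnings = report$warnings,
       config = report$config[!vapply(report$config, is.null, TRUE)],
       results = report$results)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s%s\n", nm, x$stages[[nm]]$status,
                if (!is.null(x$stages[[nm]]$seconds))
                  sprintf(" (%.2f s)", x$stages[[nm]]$seconds) else ""))
  cat(sprintf("  %d vessel measurement(s), %d warning(s)\n",
              nrow(x$results), length(x$warnings)))
  if (nrow(x$results)) print(x$results, row.names = FALSE)
  if (length(x$warnings)) cat("  warnings:",
                              paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
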