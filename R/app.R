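#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end pipeline uses. Exactly one
#' input source must be given: a TIFF+JSON pair on disk, an in-memory
#' [volume5d()], or per-frame detection lists (e.g. ground truth from the
#' simulator, skipping segmentation).
#'
#' @param image_path,metadata_path Input volume on disk.
#' @param volume In-memory [volume5d()].
#' @param detections Per-frame detection lists (skips segmentation).
#' @param spacing Required with `detections`.
#' @param denoise Run denoising before thresholding (default TRUE).
#' @param segmentation A [segmentation_params()].
#' @param cost A [cost_params()].
#' @param seed Integer seed recorded with the run.
#' @param out_dir If non-NULL, results are persisted there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(image_path = NULL, metadata_path = NULL,
                            volume = NULL, detections = NULL, spacing = NULL,
                            denoise = TRUE,
                            segmentation = segmentation_params(),
                            cost = cost_params(), seed = 0L, out_dir = NULL) {
  n_src <- (!is.null(image_path)) + (!is.null(volume)) + (!is.null(detections))
  if (n_src != 1L)
    stop("exactly one of image_path, volume, detections must be supplied")
  if (!is.null(image_path) && is.null(metadata_path))
    stop("metadata_path is required with image_path")
  if (!is.null(detections) && is.null(spacing))
    stop("spacing is required with detection-list input")
  structure(list(image_path = image_path, metadata_path = metadata_path,
                 volume = volume, detections = detections, spacing = spacing,
                 denoise = isTRUE(denoise), segmentation = segmentation,
                 cost = cost, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the off-line stages in order - background noise removal,
#' segmentation (with vessel distance maps), multitemporal association
#' tracking, lineaging with vessel-distance series - and optionally persists
#' every output. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_state`: `detections` (per frame),
#'   `distance_maps`, `tracking`, `lineage`, `spacing`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dmaps <- NULL
  if (!is.null(config$detections)) {
    dets <- config$detections
    spacing <- config$spacing
  } else {
    vol <- if (!is.null(config$volume)) config$volume else
      load_volume(config$image_path, config$metadata_path)
    spacing <- vol$spacing
    seg <- tryCatch(
      segment_movie(vol, config$segmentation, denoise = config$denoise),
      error = function(e) stop("segmentation stage failed: ",
                               conditionMessage(e)))
    dets <- seg$detections
    dmaps <- seg$distance_maps
  }
  tracking <- tryCatch(
    track_movie(dets, spacing, config$cost),
    error = function(e) stop("tracking stage failed: ", conditionMessage(e)))
  lineage <- tryCatch(
    lineage_movie(tracking, dmaps),
    error = function(e) stop("lineaging stage failed: ", conditionMessage(e)))
  state <- structure(list(detections = dets, distance_maps = dmaps,
                          tracking = tracking, lineage = lineage,
                          spacing = spacing, config = config),
                     class = "pipeline_state")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_results(lineage$forest$tracks, lineage$forest,
                 file.path(config$out_dir, "results.json"), spacing)
    export_detections_csv(lineage$forest$tracks, lineage$forest,
                          file.path(config$out_dir, "detections.csv"))
    if (!is.null(lineage$niche)) {
      niche_rows <- do.call(rbind, lapply(names(lineage$niche), function(id)
        cbind(track = as.integer(id), lineage$niche[[id]])))
      utils::write.csv(niche_rows,
                       file.path(config$out_dir, "niche_series.csv"),
                       row.names = FALSE)
    }
  }
  state
}

#' @export
print.pipeline_state <- function(x, ...) {
  n_det <- sum(vapply(x$detections, length, integer(1)))
  cat(sprintf("pipeline state: %d frames, %d detections, %d track(s), %d tree(s)\n",
              length(x$detections), n_det,
              length(x$lineage$forest$tracks), length(x$lineage$forest$trees)))
  invisible(x)
}

#' Draw a vessel-distance-encoded lineage tree
#'
#' 2-D lineage figure: time runs downward on the vertical axis (root at the
#' top); the horizontal position of each track's polyline at every frame is
#' that cell's distance to its nearest vessel, so a branch drifting toward
#' x = 0 is a cell moving into vessel contact. Divisions are horizontal
#' connectors at the division frame. Colors are keyed by track id and the
#' layout is deterministic.
#'
#' @param lineage A `lineage_result` with niche series.
#' @param tree Root id of the tree to draw, or `"largest"`.
#' @param path Output figure path; format chosen by extension
#'   (`.pdf`, `.svg`, `.png`).
#' @param frame_interval_min Minutes per frame for the time axis.
#' @return Invisibly, the track ids drawn.
#' @export
render_lineage <- function(lineage, tree = "largest", path,
                           frame_interval_min = 20) {
  if (is.null(lineage$niche))
    stop("lineage result carries no vessel-distance series; rerun with distance maps")
  forest <- lineage$forest
  root <- if (identical(tree, "largest")) largest_tree(forest) else as.integer(tree)
  key <- as.character(root)
  if (!key %in% names(forest$trees)) stop("no tree rooted at track ", root)
  ids <- forest$trees[[key]]
  by_id <- stats::setNames(forest$tracks,
                           vapply(forest$tracks, function(t) as.character(t$id), ""))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = 6, height = 6),
         svg = grDevices::svg(path, width = 6, height = 6),
         png = grDevices::png(path, width = 900, height = 900, res = 150),
         stop("unsupported figure format: .", ext))
  on.exit(grDevices::dev.off())
  series <- lapply(as.character(ids), function(id) lineage$niche[[id]])
  all_t <- range(unlist(lapply(series, function(s) s$frame)))
  all_d <- range(0, unlist(lapply(series, function(s) s$distance_um)))
  cols <- grDevices::hcl.colors(max(length(ids), 3), "Dark 3")
  graphics::plot(NA, xlim = all_d + c(0, 1), ylim = rev(all_t),
                 xlab = "distance to nearest vessel (um)",
                 ylab = sprintf("frame (%g min each)", frame_interval_min),
                 main = sprintf("clone rooted at track %d", root))
  for (k in seq_along(ids)) {
    s <- series[[k]]
    graphics::lines(s$distance_um, s$frame, col = cols[k], lwd = 2)
    graphics::points(s$distance_um, s$frame, col = cols[k], pch = 16, cex = 0.4)
  }
  # division connectors
  for (p in intersect(names(forest$division_frame), as.character(ids))) {
    kids <- names(forest$parent)[!is.na(forest$parent) &
                                   forest$parent == as.integer(p)]
    if (length(kids) < 2) next
    b <- forest$division_frame[[p]] + 1L
    xs <- vapply(kids, function(kid) {
      s <- lineage$niche[[kid]]
      s$distance_um[s$frame == b][1]
    }, numeric(1))
    graphics::segments(min(xs, na.rm = TRUE), b, max(xs, na.rm = TRUE), b,
                       lty = 2, col = "grey40")
  }
  invisible(ids)
}
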