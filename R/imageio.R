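#' Load a 5-D volume from a multi-page TIFF plus JSON sidecar
#'
#' The TIFF holds one z-plane per page, pages ordered frame-major, then
#' channel, then z. The JSON sidecar carries the physical calibration
#' (micrometres per voxel, frame interval), the channel roles, the 5-D shape
#' and the intensity storage mode. Distances downstream are physical, so a
#' sidecar without complete spacing is a hard error.
#'
#' @param image_path Path to the multi-page TIFF.
#' @param metadata_path Path to the JSON sidecar written by [save_volume()].
#' @return A [volume5d()].
#' @export
load_volume <- function(image_path, metadata_path) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  meta <- jsonlite::fromJSON(metadata_path, simplifyVector = TRUE)
  for (f in c("dx", "dy", "dz"))
    if (is.null(meta[[f]]) || !is.finite(meta[[f]]))
      stop("metadata lacks voxel spacing field '", f,
           "' (", metadata_path, "); physical distances are impossible without it")
  spacing <- voxel_spacing(meta$dx, meta$dy, meta$dz)
  shape <- as.integer(meta$shape)  # (t, channel, z, y, x)
  if (length(shape) != 5L)
    stop("metadata 'shape' must have 5 entries (t, channel, z, y, x): ",
         metadata_path)
  storage_mode <- if (is.null(meta$storage)) "uint16" else meta$storage
  as_is <- identical(storage_mode, "uint16")
  pages <- tiff::readTIFF(image_path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != prod(shape[1:3]))
    stop("page count mismatch in ", image_path, ": expected ",
         prod(shape[1:3]), " (t*channel*z) pages, found ", length(pages))
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  data <- array(0, dim = shape)
  p <- 1L
  for (t in seq_len(shape[1]))
    for (ch in seq_len(shape[2]))
      for (z in seq_len(shape[3])) {
        pg <- pages[[p]]
        if (!identical(dim(pg)[1:2], shape[4:5]))
          stop("page ", p, " of ", image_path, " has dimensions ",
               paste(dim(pg), collapse = "x"), ", expected ",
               shape[4], "x", shape[5])
        data[t, ch, z, , ] <- if (as_is) pg else pg * scale
        p <- p + 1L
      }
  roles <- rep("other", shape[2])
  if (!is.null(meta$channels) && length(meta$channels))
    roles[meta$channels$index] <- meta$channels$role
  volume5d(data, spacing,
           frame_interval_min = if (is.null(meta$frame_interval_min)) 20
                                else meta$frame_interval_min,
           channel_roles = roles)
}

#' Save a 5-D volume as multi-page TIFF plus JSON sidecar
#'
#' Integer-valued volumes within 16-bit range are stored as 16-bit pages and
#' round-trip bit-exactly through [load_volume()]. Other volumes are stored
#' as 32-bit float pages scaled into `[0, 1]` by a factor recorded in the
#' sidecar (round-trip exact to single precision).
#'
#' @param vol A [volume5d()].
#' @param image_path,metadata_path Output paths.
#' @param extra Optional named list merged into the sidecar (e.g. tile stage
#'   positions, updated montage dimensions).
#' @export
save_volume <- function(vol, image_path, metadata_path, extra = list()) {
  stopifnot(inherits(vol, "volume5d"))
  d <- dim(vol$data)
  if (any(d == 0)) stop("cannot save a volume with a zero-length axis")
  integral <- max(vol$data) <= 65535 &&
    isTRUE(all(vol$data == round(vol$data)))
  storage_mode <- if (integral) "uint16" else "float32"
  scale <- if (integral) 65535 else max(vol$data, 1)
  pages <- vector("list", prod(d[1:3]))
  p <- 1L
  for (t in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      for (z in seq_len(d[3])) {
        pages[[p]] <- matrix(vol$data[t, ch, z, , ] / scale, d[4], d[5])
        p <- p + 1L
      }
  bits <- if (integral) 16L else 32L
  ok <- tiff::writeTIFF(pages, image_path, bits.per.sample = bits)
  if (!isTRUE(ok > 0)) stop("failed to write TIFF: ", image_path)
  meta <- c(list(
    dx = vol$spacing$dx, dy = vol$spacing$dy, dz = vol$spacing$dz,
    frame_interval_min = vol$frame_interval_min,
    shape = d,
    storage = storage_mode,
    intensity_scale = if (integral) 1 else scale,
    channels = data.frame(index = seq_len(d[2]), role = vol$channel_roles)
  ), extra)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

.serialize_detection <- function(det) {
  list(frame = det$frame, id = det$id,
       voxels = unname(det$voxels),
       voxel_count = det$voxel_count,
       centroid_um = unname(det$centroid_um),
       volume_um3 = det$volume_um3)
}

#' Persist tracking and lineage results as JSON
#'
#' Writes every track (with each detection's frame, voxel set, centroid and
#' volume) plus the lineage forest (parent links and division frames) to a
#' single JSON document. [load_results()] reproduces the in-memory
#' structures exactly.
#'
#' @param tracks List of track objects from [track_movie()].
#' @param lineage A lineage forest from [build_forest()], or `NULL`.
#' @param path Output path.
#' @param spacing The [voxel_spacing()] of the source volume.
#' @export
save_results <- function(tracks, lineage, path, spacing) {
  track_ids <- vapply(tracks, function(tr) tr$id, integer(1))
  if (!is.null(lineage)) {
    pp <- lineage$parent[!is.na(lineage$parent)]
    bad <- setdiff(unique(c(as.integer(names(pp)), unname(pp))), track_ids)
    if (length(bad))
      stop("lineage refers to track id(s) absent from `tracks`: ",
           paste(bad, collapse = ", "))
  }
  doc <- list(
    index_base = 1,
    spacing = list(dx = spacing$dx, dy = spacing$dy, dz = spacing$dz),
    tracks = lapply(tracks, function(tr) list(
      id = tr$id,
      detections = lapply(tr$detections, .serialize_detection)
    )),
    lineage = if (is.null(lineage)) NULL else list(
      parent = as.list(stats::setNames(
        ifelse(is.na(lineage$parent), -1L, lineage$parent),
        names(lineage$parent))),
      division_frame = as.list(lineage$division_frame)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' @rdname save_results
#' @return `load_results()` returns `list(tracks, lineage, spacing)`.
#' @export
load_results <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  spacing <- voxel_spacing(doc$spacing$dx, doc$spacing$dy, doc$spacing$dz)
  tracks <- lapply(doc$tracks, function(tr) {
    dets <- lapply(tr$detections, function(d) {
      vox <- matrix(as.integer(unlist(d$voxels)), ncol = 3, byrow = TRUE)
      detection(d$frame, vox, spacing, id = d$id)
    })
    names(dets) <- vapply(dets, function(d) as.character(d$frame), "")
    new_track(as.integer(tr$id), dets)
  })
  lineage <- NULL
  if (!is.null(doc$lineage)) {
    par <- unlist(doc$lineage$parent)
    par <- stats::setNames(ifelse(par < 0, NA_integer_, as.integer(par)),
                           names(doc$lineage$parent))
    div <- unlist(doc$lineage$division_frame)
    lineage <- build_forest(tracks, par)
    if (!is.null(div)) lineage$division_frame[names(div)] <- as.integer(div)
  }
  list(tracks = tracks, lineage = lineage, spacing = spacing)
}

#' Export detections as a flat CSV table
#'
#' One row per detection: frame, track id, centroid (x, y, z um), volume and
#' parent track id (-1 for roots), for use outside R.
#'
#' @param tracks List of tracks.
#' @param lineage Lineage forest or `NULL`.
#' @param path Output CSV path.
#' @export
export_detections_csv <- function(tracks, lineage, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    parent <- if (is.null(lineage)) NA_integer_ else
      lineage$parent[[as.character(tr$id)]]
    do.call(rbind, lapply(tr$detections, function(d) {
      data.frame(frame = d$frame, track_id = tr$id,
                 cx = d$centroid_um[1], cy = d$centroid_um[2],
                 cz = d$centroid_um[3], volume_um3 = d$volume_um3,
                 parent_track = ifelse(is.na(parent), -1L, parent))
    }))
  }))
  rows <- rows[order(rows$frame, rows$track_id), ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
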