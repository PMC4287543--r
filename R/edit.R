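#' Split a detection into n cells by Gaussian-mixture fitting
#'
#' Fits a full-covariance mixture of n Gaussians to the detection's voxel
#' physical coordinates and assigns every voxel to its maximum-posterior
#' component. Full-covariance Gaussian decision boundaries favour the
#' ellipsoidal shapes of 3-D cell somata (unlike k-means, which favours
#' spheres). The union of the outputs is exactly the input voxel set.
#' Resulting parts below the minimum-volume filter are warned about but kept
#' - the split is user intent. An empty component triggers up to five
#' re-fits with perturbed initialisation before erroring.
#'
#' @param det A [detection()] with at least `4 * n` voxels.
#' @param n Number of cells to split into (>= 2).
#' @param spacing A [voxel_spacing()].
#' @param seed Integer seed making the fit reproducible.
#' @param min_volume_um3 Volume filter used only for the warning.
#' @return List of `n` [detection()]s (same frame), ordered by scan-order
#'   first voxel.
#' @importFrom mclust Mclust mclustBIC
#' @export
split_detection <- function(det, n, spacing, seed = 0,
                            min_volume_um3 = 19) {
  if (n < 2) stop("`n` must be >= 2")
  if (det$voxel_count < 4 * n)
    stop("detection has ", det$voxel_count, " voxels; need at least ",
         4 * n, " to split into ", n)
  pts <- voxel_coords_um(det$voxels, spacing)
  cls <- NULL
  for (attempt in 0:5) {
    set.seed(seed + attempt)
    fit <- tryCatch({
      if (attempt == 0) {
        mclust::Mclust(pts, G = n, modelNames = "VVV", verbose = FALSE)
      } else {
        sub <- sample(nrow(pts), max(4 * n, ceiling(nrow(pts) / 2)))
        mclust::Mclust(pts, G = n, modelNames = "VVV", verbose = FALSE,
                       initialization = list(subset = sub))
      }
    }, error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$classification) &&
        length(unique(fit$classification)) == n) {
      cls <- fit$classification
      break
    }
  }
  if (is.null(cls))
    stop("Gaussian-mixture split produced an empty component after 6 attempts")
  parts <- lapply(sort(unique(cls)), function(k)
    detection(det$frame, det$voxels[cls == k, , drop = FALSE], spacing))
  vols <- vapply(parts, function(p) p$volume_um3, numeric(1))
  if (any(vols < min_volume_um3))
    warning("split produced ", sum(vols < min_volume_um3),
            " part(s) below the ", min_volume_um3,
            " um^3 volume filter; kept (user intent wins)")
  dims <- c(max(det$voxels[, 1]), max(det$voxels[, 2]), max(det$voxels[, 3]))
  keys <- vapply(parts, .det_order_key, numeric(1), dims = dims)
  parts[order(keys)]
}

#' An editing event
#'
#' @param kind One of `"split"`, `"delete"`.
#' @param frame Frame of the edited detection.
#' @param detection_id Index of the target detection within that frame.
#' @param n Number of parts for a split.
#' @param seed Seed for the mixture fit.
#' @return A list of class `edit_event`.
#' @export
edit_event <- function(kind = c("split", "delete"), frame, detection_id,
                       n = 2L, seed = 0L) {
  kind <- match.arg(kind)
  if (kind == "split" && n < 2) stop("split requires n >= 2")
  structure(list(kind = kind, frame = as.integer(frame),
                 detection_id = as.integer(detection_id),
                 n = as.integer(n), seed = as.integer(seed)),
            class = "edit_event")
}

#' Delete a detection from the per-frame detection lists
#'
#' Removes the detection; the owning track is truncated or split at the gap
#' by the subsequent tracking rerun (occlusion rules decide whether the gap
#' is bridged).
#'
#' @param dets_by_frame Per-frame detection lists.
#' @param frame Frame index.
#' @param detection_id Index of the detection within the frame.
#' @return Updated per-frame detection lists (ids renumbered within frame).
#' @export
delete_detection <- function(dets_by_frame, frame, detection_id) {
  if (frame < 1 || frame > length(dets_by_frame))
    stop("frame out of range")
  if (detection_id < 1 || detection_id > length(dets_by_frame[[frame]]))
    stop("no detection ", detection_id, " in frame ", frame)
  dets_by_frame[[frame]][[detection_id]] <- NULL
  dets_by_frame[[frame]] <- .renumber(dets_by_frame[[frame]])
  dets_by_frame
}

.renumber <- function(dets) {
  for (k in seq_along(dets)) dets[[k]]$id <- k
  dets
}

# BIC comparison: does an n-component full-covariance mixture explain the
# detection's voxel cloud better than a single Gaussian?
.looks_merged <- function(det, n, spacing, seed = 0) {
  if (det$voxel_count < 4 * n) return(FALSE)
  pts <- voxel_coords_um(det$voxels, spacing)
  set.seed(seed)
  bic <- tryCatch(
    mclust::mclustBIC(pts, G = c(1, n), modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(bic) || any(!is.finite(bic[, 1]))) return(FALSE)
  bic[2, 1] > bic[1, 1]
}

# track (from a tracking_result) owning detection `j` of frame `f`, or NULL
.owning_track <- function(tracking, f, j) {
  for (tr in tracking$tracks) {
    key <- as.character(f)
    if (key %in% names(tr$detections) && identical(tr$detections[[key]]$id, j))
      return(tr)
  }
  NULL
}

#' Apply an edit and propagate it forward
#'
#' Applies a user edit to one frame and, for a split, walks the original
#' track's assignments forward as automated correction candidates: at each
#' subsequent frame, if the tracked detection still looks like the same
#' merge - its volume exceeds 75% of the split parts' combined volume and it
#' is the minimum-cost successor of at least two of the parts - it is
#' auto-split with the same n (seed derived from the user's seed plus the
#' frame offset). Propagation stops at the first frame where the parts
#' acquire distinct successors (the new cell has established its own track).
#' Tracking and lineaging are then rerun on the edited detections; frames
#' before the edit are never touched.
#'
#' @param dets_by_frame Per-frame detection lists (e.g. from
#'   [segment_movie()]).
#' @param tracking The `tracking_result` computed before the edit.
#' @param edit An [edit_event()].
#' @param params A [cost_params()].
#' @param spacing A [voxel_spacing()].
#' @param volume_ratio Merge-consistency volume threshold (default 0.75).
#' @return List: `dets_by_frame` (edited), `tracking` (rerun),
#'   `auto_edited_frames` (frames corrected beyond the user's own edit).
#' @export
propagate_edit <- function(dets_by_frame, tracking, edit,
                           params = cost_params(),
                           spacing = tracking$spacing,
                           volume_ratio = 0.75) {
  stopifnot(inherits(edit, "edit_event"))
  auto <- integer(0)
  if (edit$kind == "delete") {
    dets_by_frame <- delete_detection(dets_by_frame, edit$frame,
                                      edit$detection_id)
  } else {
    f <- edit$frame
    target <- dets_by_frame[[f]][[edit$detection_id]]
    owner <- .owning_track(tracking, f, edit$detection_id)
    parts <- split_detection(target, edit$n, spacing, seed = edit$seed)
    dets_by_frame[[f]] <- .renumber(c(dets_by_frame[[f]][-edit$detection_id],
                                      parts))
    repeat {
      f_next <- f + 1L
      if (is.null(owner) || f_next > length(dets_by_frame)) break
      key <- as.character(f_next)
      if (!key %in% names(owner$detections)) break
      succ_id <- owner$detections[[key]]$id
      succ <- dets_by_frame[[f_next]][[succ_id]]
      combined <- sum(vapply(parts, function(p) p$volume_um3, numeric(1)))
      if (succ$volume_um3 <= volume_ratio * combined) break
      # the successor must itself look multimodal: an n-component mixture has
      # to beat a single component on BIC, otherwise it is one true cell
      if (!.looks_merged(succ, edit$n, spacing,
                         seed = edit$seed + (f_next - edit$frame))) break
      # is the successor the nearest next-frame detection of >= 2 parts?
      nearest <- vapply(parts, function(p) {
        costs <- vapply(dets_by_frame[[f_next]], function(d)
          .link_cost(p, d, spacing, params), numeric(1))
        if (!any(is.finite(costs))) NA_integer_ else which.min(costs)
      }, integer(1))
      if (sum(nearest == succ_id, na.rm = TRUE) < 2L) break
      parts <- split_detection(succ, edit$n, spacing,
                               seed = edit$seed + (f_next - edit$frame))
      dets_by_frame[[f_next]] <- .renumber(c(dets_by_frame[[f_next]][-succ_id],
                                             parts))
      auto <- c(auto, f_next)
      f <- f_next
    }
  }
  list(dets_by_frame = dets_by_frame,
       tracking = track_movie(dets_by_frame, spacing, params),
       auto_edited_frames = auto)
}
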