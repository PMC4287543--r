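#' Assign a parent to a newborn track
#'
#' A track born after the first frame is assigned the parent that was
#' cheapest to divide from: over all tracks with a detection in the frame
#' before the newborn's birth, the one whose stored single-link cost (the
#' same connected-component x size cost used by the tracker) to the
#' newborn's first detection is minimal. If every candidate is infeasible
#' the newborn stays a root.
#'
#' @param newborn A [new_track()] born after frame 1.
#' @param tracking A `tracking_result` from [track_movie()].
#' @return Parent track id, or `NA` if none is feasible.
#' @export
assign_parent <- function(newborn, tracking) {
  b <- newborn$birth
  if (b <= 1L) return(NA_integer_)
  rec <- tracking$assoc[[b]]
  if (is.null(rec)) return(NA_integer_)
  first_det <- newborn$detections[[1]]
  j <- first_det$id
  if (is.na(j) || j < 1 || j > ncol(rec$link_costs)) return(NA_integer_)
  cand <- which(rec$track_last_frame == b - 1L & rec$track_ids != newborn$id)
  if (length(cand) == 0L) return(NA_integer_)
  costs <- rec$link_costs[cand, j]
  if (!any(is.finite(costs))) return(NA_integer_)
  o <- order(costs, rec$track_ids[cand])
  rec$track_ids[cand][o[1]]
}

#' Build a lineage forest from tracks and parent assignments
#'
#' Tracks linked by parent-daughter (division) edges. A division splits the
#' parent: when a newborn is assigned parent P at birth frame b and P still
#' has detections at frames >= b (the tracker extended P straight into one
#' daughter), P is cut at b - its tail becomes a new daughter track - so
#' every parent ends exactly one frame before its daughters are born and
#' each division yields two daughters. A division with a third concurrent
#' daughter is flagged (validation, not an error); a cyclic parent
#' assignment is an error.
#'
#' @param tracks List of [new_track()] objects.
#' @param parents Named integer vector: track id -> parent id (`NA` = root).
#' @return Object of class `lineage_forest`: `tracks` (including split
#'   tails), `parent`, `division_frame` (parent id -> its end frame),
#'   `trees` (list of track-id vectors, one per root), `root` per tree,
#'   `flags` (character vector of validation notes).
#' @export
build_forest <- function(tracks, parents) {
  if (length(tracks) == 0L)
    return(structure(list(tracks = list(), parent = integer(0),
                          division_frame = integer(0), trees = list(),
                          flags = character(0)),
                     class = "lineage_forest"))
  by_id <- stats::setNames(tracks, vapply(tracks, function(t) as.character(t$id), ""))
  parent_map <- stats::setNames(rep(NA_integer_, length(by_id)), names(by_id))
  if (length(parents))
    parent_map[names(parents)] <- parents
  # cycle check on the original assignment
  for (id in names(parent_map)) {
    seen <- character(0); cur <- id
    while (!is.na(parent_map[[cur]])) {
      if (cur %in% seen) stop("cycle in parent assignments at track ", cur)
      seen <- c(seen, cur)
      cur <- as.character(parent_map[[cur]])
      if (!cur %in% names(parent_map)) stop("unknown parent id ", cur)
    }
  }
  division_frame <- integer(0)
  succ <- character(0)  # parent segment id -> tail segment id after a split
  flags <- character(0)
  next_id <- max(vapply(by_id, function(t) t$id, integer(1))) + 1L
  newborn_ids <- names(parent_map)[!is.na(parent_map)]
  births <- vapply(newborn_ids, function(id) by_id[[id]]$birth, integer(1))
  for (id in newborn_ids[order(births, as.integer(newborn_ids))]) {
    b <- by_id[[id]]$birth
    p <- as.character(parent_map[[id]])
    while (by_id[[p]]$end < b - 1L && !is.na(succ[p]))
      p <- succ[[p]]
    if (by_id[[p]]$end < b - 1L) {
      flags <- c(flags, sprintf(
        "track %s: parent %s has no detection at frame %d; kept as assigned",
        id, p, b - 1L))
    }
    if (by_id[[p]]$end >= b) {
      frames <- as.integer(names(by_id[[p]]$detections))
      tail_dets <- by_id[[p]]$detections[frames >= b]
      head_dets <- by_id[[p]]$detections[frames < b]
      tail_tr <- new_track(next_id, tail_dets)
      by_id[[p]] <- new_track(by_id[[p]]$id, head_dets)
      by_id[[as.character(next_id)]] <- tail_tr
      parent_map[[as.character(next_id)]] <- by_id[[p]]$id
      succ[p] <- as.character(next_id)
      next_id <- next_id + 1L
    }
    parent_map[[id]] <- by_id[[p]]$id
    division_frame[p] <- by_id[[p]]$end
    n_daughters <- sum(parent_map == by_id[[p]]$id, na.rm = TRUE)
    if (n_daughters > 2)
      flags <- c(flags, sprintf("track %s has %d concurrent daughters", p, n_daughters))
  }
  roots <- names(parent_map)[is.na(parent_map)]
  root_of <- function(id) {
    while (!is.na(parent_map[[id]])) id <- as.character(parent_map[[id]])
    id
  }
  membership <- vapply(names(parent_map), root_of, "")
  trees <- split(as.integer(names(parent_map)), membership)
  trees <- trees[order(as.integer(names(trees)))]
  structure(list(tracks = unname(by_id[order(vapply(by_id, function(t) t$id, integer(1)))]),
                 parent = parent_map[order(as.integer(names(parent_map)))],
                 division_frame = division_frame,
                 trees = trees,
                 flags = flags),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("lineage forest: %d track(s) in %d tree(s), %d division(s)\n",
              length(x$tracks), length(x$trees), length(x$division_frame)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Largest lineage tree
#'
#' The tree with the most track nodes: the one presented first, expected to
#' be either the most interesting clone or the one needing the most edits.
#' Ties go to the earliest root birth, then the lowest root id.
#'
#' @param forest A [build_forest()] result.
#' @return Root track id (names the tree) as integer.
#' @export
largest_tree <- function(forest) {
  if (length(forest$trees) == 0L) stop("empty lineage forest")
  sizes <- vapply(forest$trees, length, integer(1))
  by_id <- stats::setNames(forest$tracks,
                           vapply(forest$tracks, function(t) as.character(t$id), ""))
  root_ids <- as.integer(names(forest$trees))
  births <- vapply(names(forest$trees), function(r) by_id[[r]]$birth, integer(1))
  o <- order(-sizes, births, root_ids)
  root_ids[o[1]]
}

#' Per-frame distance of a track to the nearest vessel
#'
#' For every detection of the track, the minimum of the vessel distance map
#' over the detection's voxel set: the cell-surface-to-vessel distance, zero
#' when the cell touches vessel foreground.
#'
#' @param track A [new_track()].
#' @param distance_maps Per-frame list of distance maps
#'   ([vessel_distance_map()]).
#' @return Data frame with columns `frame`, `distance_um`.
#' @export
niche_series <- function(track, distance_maps) {
  frames <- as.integer(names(track$detections))
  dist <- vapply(seq_along(frames), function(k) {
    f <- frames[k]
    if (f > length(distance_maps) || is.null(distance_maps[[f]]))
      stop("no distance map for frame ", f)
    dm <- distance_maps[[f]]
    v <- track$detections[[k]]$voxels
    min(dm[v])
  }, numeric(1))
  data.frame(frame = frames, distance_um = dist)
}

#' Cleavage plane between two daughter cells
#'
#' The perpendicular bisector of the daughters' first-frame centroids: the
#' plane through their midpoint whose unit normal points along the
#' centroid-difference vector. When a vessel distance map is supplied, the
#' angle between the plane normal and the direction from the midpoint to the
#' nearest vessel voxel (the zero set of the map) is also reported, folded
#' into `[0, 90]` degrees.
#'
#' @param daughter_a,daughter_b First-frame [detection()]s of the daughters
#'   (same birth frame, distinct centroids).
#' @param distance_map Optional vessel distance map for the birth frame.
#' @param spacing A [voxel_spacing()] (required with `distance_map`).
#' @return List of class `cleavage_plane`: `point` (x, y, z um), `normal`
#'   (unit vector), and `vessel_angle_deg` when a map was supplied.
#' @export
cleavage_plane <- function(daughter_a, daughter_b, distance_map = NULL,
                           spacing = NULL) {
  if (daughter_a$frame != daughter_b$frame)
    stop("daughters must share their birth frame")
  ca <- daughter_a$centroid_um; cb <- daughter_b$centroid_um
  diff <- cb - ca
  nn <- sqrt(sum(diff^2))
  if (nn == 0) stop("coincident daughter centroids: cleavage plane undefined")
  out <- list(point = (ca + cb) / 2, normal = diff / nn)
  if (!is.null(distance_map)) {
    stopifnot(!is.null(spacing))
    fg <- which(distance_map == 0)
    if (length(fg)) {
      d <- dim(distance_map)
      zz <- (fg - 1) %% d[1] + 1
      yy <- ((fg - 1) %/% d[1]) %% d[2] + 1
      xx <- (fg - 1) %/% (d[1] * d[2]) + 1
      vpts <- voxel_coords_um(cbind(zz, yy, xx), spacing)
      rel <- sweep(vpts, 2, out$point)
      k <- which.min(rowSums(rel^2))
      v <- rel[k, ]
      vn <- sqrt(sum(v^2))
      if (vn > 0) {
        cosang <- abs(sum(out$normal * v) / vn)
        out$vessel_angle_deg <- acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
      }
    }
  }
  structure(out, class = "cleavage_plane")
}

#' Lineage a tracked movie
#'
#' Assigns parents to every track born after frame 1, builds the division
#' forest (splitting parent tracks at divisions), and - when distance maps
#' are available - attaches per-track vessel-distance series and per-division
#' cleavage planes.
#'
#' @param tracking A `tracking_result` from [track_movie()].
#' @param distance_maps Optional per-frame vessel distance maps.
#' @return List of class `lineage_result`: `forest`, `niche` (named list of
#'   [niche_series()] data frames), `cleavage` (per-division planes).
#' @export
lineage_movie <- function(tracking, distance_maps = NULL) {
  tracks <- tracking$tracks
  parents <- integer(0)
  for (tr in tracks) {
    if (tr$birth > 1L) {
      p <- assign_parent(tr, tracking)
      if (!is.na(p)) parents[as.character(tr$id)] <- p
    }
  }
  forest <- build_forest(tracks, parents)
  niche <- NULL
  cleavage <- NULL
  if (!is.null(distance_maps)) {
    niche <- lapply(forest$tracks, niche_series, distance_maps = distance_maps)
    names(niche) <- vapply(forest$tracks, function(t) as.character(t$id), "")
    by_id <- stats::setNames(forest$tracks, names(niche))
    cleavage <- list()
    for (p in names(forest$division_frame)) {
      kids <- names(forest$parent)[!is.na(forest$parent) &
                                     forest$parent == as.integer(p)]
      if (length(kids) == 2L) {
        b <- forest$division_frame[[p]] + 1L
        d1 <- by_id[[kids[1]]]$detections[[1]]
        d2 <- by_id[[kids[2]]]$detections[[1]]
        dm <- if (b <= length(distance_maps)) distance_maps[[b]] else NULL
        cleavage[[p]] <- tryCatch(
          cleavage_plane(d1, d2, dm, tracking$spacing),
          error = function(e) NULL)
      }
    }
  }
  structure(list(forest = forest, niche = niche, cleavage = cleavage),
            class = "lineage_result")
}
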