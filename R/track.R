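#' Construct a track
#'
#' A temporally ordered chain of detections sharing one identity.
#'
#' @param id Integer track id.
#' @param detections Named list of [detection()]s, names = frame indices.
#' @return Object of class `track` with `id`, `detections`, `birth`, `end`.
#' @export
new_track <- function(id, detections) {
  frames <- as.integer(names(detections))
  if (length(frames) == 0L) stop("a track needs at least one detection")
  o <- order(frames)
  if (any(duplicated(frames))) stop("duplicate frames in track")
  structure(list(id = as.integer(id), detections = detections[o],
                 birth = min(frames), end = max(frames)),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track %d: frames %d-%d (%d detections)\n",
              x$id, x$birth, x$end, length(x$detections)))
  invisible(x)
}

#' Tracking cost parameters
#'
#' @param W Window size in frames for the multitemporal cost (default 4).
#' @param lambda Weight of the size-distance term (dimensionless, default 1).
#' @param max_link_distance Largest physical gap (micrometres) a single
#'   frame-to-frame link may span; larger links are infeasible. Default 30.
#' @param occlusion_gap Frames a track may go undetected and still be
#'   extended (default 1).
#' @return A list of class `cost_params`.
#' @export
cost_params <- function(W = 4, lambda = 1, max_link_distance = 30,
                        occlusion_gap = 1) {
  if (W < 1 || lambda < 0 || max_link_distance <= 0 || occlusion_gap < 0)
    stop("invalid cost parameters")
  structure(list(W = as.integer(W), lambda = lambda,
                 max_link_distance = max_link_distance,
                 occlusion_gap = as.integer(occlusion_gap)),
            class = "cost_params")
}

#' Connected-component distance between two detections
#'
#' Minimum Euclidean distance, in micrometres, over all pairs of foreground
#' voxel centers of the two detections (scaled by the voxel spacing, so
#' anisotropy is respected). Zero when the voxel sets overlap.
#'
#' @param a,b [detection()] objects.
#' @param spacing A [voxel_spacing()].
#' @return Scalar distance in micrometres.
#' @export
cc_distance <- function(a, b, spacing) {
  cpp_min_pair_dist(voxel_coords_um(a$voxels, spacing),
                    voxel_coords_um(b$voxels, spacing))
}

#' Size distance between two detections
#'
#' Normalized difference of foreground voxel counts,
#' `||a| - |b|| / max(|a|, |b|)`, in `[0, 1)`: zero for equal sizes. Keeps
#' sizes homogeneous along a track.
#'
#' @param a,b [detection()] objects.
#' @return Dimensionless scalar in `[0, 1)`.
#' @export
size_distance <- function(a, b) {
  abs(a$voxel_count - b$voxel_count) / max(a$voxel_count, b$voxel_count)
}

# single-link cost: cc * (1 + lambda * size); Inf beyond the feasibility gate
.link_cost <- function(a, b, spacing, params) {
  cc <- cc_distance(a, b, spacing)
  if (cc > params$max_link_distance) return(Inf)
  cc * (1 + params$lambda * size_distance(a, b))
}

#' Multitemporal cost of a track extension
#'
#' Cost of extending track `tau` by the detection sequence `rho`
#' (consecutive frames, first detection at most `occlusion_gap + 1` frames
#' after the track's end): `(W / |rho|) * sum_i d(rho[i-1], rho[i]) *
#' (1 + lambda * s(rho[i-1], rho[i]))` where `d` is [cc_distance()], `s` is
#' [size_distance()], and `rho[0]` is the track's last detection. The
#' multiplicative `W / |rho|` term discourages short extensions, which would
#' otherwise be cheap simply by having fewer terms. Any link beyond
#' `max_link_distance` makes the whole extension infeasible (`Inf`).
#'
#' @param tau A [new_track()] object.
#' @param rho List of [detection()]s in consecutive frames.
#' @param params A [cost_params()].
#' @param spacing A [voxel_spacing()].
#' @return Scalar cost (possibly `Inf`).
#' @export
path_cost <- function(tau, rho, params, spacing) {
  if (length(rho) < 1) stop("extension must contain at least one detection")
  frames <- vapply(rho, function(d) d$frame, integer(1))
  if (length(frames) > 1 && any(diff(frames) != 1L))
    stop("extension detections must occupy consecutive frames")
  if (frames[1] - tau$end > params$occlusion_gap + 1L) return(Inf)
  prev <- tau$detections[[length(tau$detections)]]
  total <- 0
  for (d in rho) {
    lc <- .link_cost(prev, d, spacing, params)
    if (!is.finite(lc)) return(Inf)
    total <- total + lc
    prev <- d
  }
  (params$W / length(rho)) * total
}

# memoized link cost between detection i in frame f1 and j in frame f2
.memo_link <- function(memo, dets_by_frame, f1, i, f2, j, spacing, params) {
  key <- paste(f1, i, f2, j, sep = ".")
  val <- memo[[key]]
  if (is.null(val)) {
    val <- .link_cost(dets_by_frame[[f1]][[i]], dets_by_frame[[f2]][[j]],
                      spacing, params)
    memo[[key]] <- val
  }
  val
}

# achievable (length, min-sum) suffixes continuing from detection j at frame f
# for `rem` more links; returns numeric vector indexed by length 0..rem
# (Inf = length unachievable). Paths are maximal: stopping early is only
# achievable at a dead end.
.suffix_sums <- function(f, j, rem, dets_by_frame, spacing, params, memo, smemo) {
  if (rem == 0L) return(0)
  key <- paste(f, j, rem, sep = ".")
  hit <- smemo[[key]]
  if (!is.null(hit)) return(hit)
  out <- rep(Inf, rem + 1L)
  n_next <- if (f + 1L <= length(dets_by_frame)) length(dets_by_frame[[f + 1L]]) else 0L
  any_feasible <- FALSE
  if (n_next > 0L) {
    for (k in seq_len(n_next)) {
      lc <- .memo_link(memo, dets_by_frame, f, j, f + 1L, k, spacing, params)
      if (!is.finite(lc)) next
      any_feasible <- TRUE
      sub <- .suffix_sums(f + 1L, k, rem - 1L, dets_by_frame, spacing, params,
                          memo, smemo)
      for (len in seq_along(sub)) {
        if (is.finite(sub[len]))
          out[len + 1L] <- min(out[len + 1L], lc + sub[len])
      }
    }
  }
  if (!any_feasible) out[1L] <- 0
  smemo[[key]] <- out
  out
}

#' Best windowed extension of a track
#'
#' Exhaustively searches detection sequences of length up to `W` starting in
#' frame `t + 1` (consecutive frames, each link within
#' `max_link_distance`), evaluating [path_cost()] for each, and reports the
#' per-first-detection minima (the tracking-graph edge costs) and the
#' overall best extension.
#'
#' @param tau A track whose extension into `t + 1` is sought.
#' @param dets_by_frame List (one entry per frame) of detection lists.
#' @param t Current frame; extensions start at `t + 1`.
#' @param params A [cost_params()].
#' @param spacing A [voxel_spacing()].
#' @return `NULL` if no feasible extension, else list with `edge_costs`
#'   (numeric, one per detection in frame `t + 1`; `Inf` = infeasible),
#'   `best_j`, `best_cost`.
#' @export
best_extension <- function(tau, dets_by_frame, t, params, spacing) {
  res <- .extension_costs(tau, dets_by_frame, t, params, spacing,
                          memo = new.env(parent = emptyenv()),
                          smemo = new.env(parent = emptyenv()))
  if (all(!is.finite(res$edge_costs))) return(NULL)
  res
}

.extension_costs <- function(tau, dets_by_frame, t, params, spacing, memo, smemo) {
  n_next <- length(dets_by_frame[[t + 1L]])
  edge_costs <- rep(Inf, n_next)
  link0 <- rep(Inf, n_next)
  L <- min(params$W, length(dets_by_frame) - t)
  last <- tau$detections[[length(tau$detections)]]
  gap_ok <- (t + 1L) - tau$end <= params$occlusion_gap + 1L
  if (gap_ok && n_next > 0L) {
    for (j in seq_len(n_next)) {
      lc <- .link_cost(last, dets_by_frame[[t + 1L]][[j]], spacing, params)
      link0[j] <- lc
      if (!is.finite(lc)) next
      sub <- .suffix_sums(t + 1L, j, L - 1L, dets_by_frame, spacing, params,
                          memo, smemo)
      for (len in seq_along(sub)) {
        if (is.finite(sub[len]))
          edge_costs[j] <- min(edge_costs[j],
                               (params$W / len) * (lc + sub[len]))
      }
    }
  }
  best_j <- if (any(is.finite(edge_costs))) which.min(edge_costs) else NA_integer_
  list(edge_costs = edge_costs, link_costs = link0,
       best_j = best_j,
       best_cost = if (is.na(best_j)) Inf else edge_costs[best_j])
}

#' Mutual-minimum matching of tracks to detections
#'
#' An edge (i, j) of the cost matrix is a matching edge when it is
#' simultaneously the minimum of its row and of its column (ties broken by
#' lower row, then lower column index). Matched tracks extend along their
#' matching edge; unmatched detections seed new tracks; unmatched tracks are
#' held for possible occlusion re-entry.
#'
#' @param costs Numeric matrix, rows = tracks, columns = detections in the
#'   next frame; `Inf` marks infeasible pairs.
#' @return List: `matches` (2-column matrix of row/column pairs),
#'   `new_detections` (column indices without an incoming match),
#'   `unextended` (row indices without a match).
#' @export
match_frame <- function(costs) {
  costs <- rbind(costs)
  nr <- nrow(costs); nc <- ncol(costs)
  matches <- NULL
  if (nr > 0 && nc > 0) {
    row_best <- apply(costs, 1, function(r)
      if (any(is.finite(r))) which.min(r) else NA_integer_)
    col_best <- apply(costs, 2, function(c)
      if (any(is.finite(c))) which.min(c) else NA_integer_)
    for (i in seq_len(nr)) {
      j <- row_best[i]
      if (!is.na(j) && !is.na(col_best[j]) && col_best[j] == i)
        matches <- rbind(matches, c(i, j))
    }
  }
  matched_rows <- if (is.null(matches)) integer(0) else matches[, 1]
  matched_cols <- if (is.null(matches)) integer(0) else matches[, 2]
  list(matches = matches,
       new_detections = setdiff(seq_len(nc), matched_cols),
       unextended = setdiff(seq_len(nr), matched_rows))
}

#' Track a movie by multitemporal association
#'
#' Frame-sequential tracking: for every frame transition the windowed
#' extension costs of all live tracks are computed ([best_extension()]),
#' tracks extend along mutual-minimum matching edges ([match_frame()]),
#' unmatched detections seed new tracks, and unmatched tracks stay live for
#' up to `occlusion_gap` frames before closing. Every detection ends up in
#' exactly one track. The per-frame association records (windowed edge costs
#' and single-link costs) are retained for lineaging.
#'
#' @param dets_by_frame List (one entry per frame) of [detection()] lists.
#' @param spacing A [voxel_spacing()].
#' @param params A [cost_params()].
#' @return List of class `tracking_result`: `tracks` (list of [new_track()]
#'   objects, ids in creation order), `assoc` (per-frame association
#'   records), `params`, `spacing`.
#' @export
track_movie <- function(dets_by_frame, spacing, params = cost_params()) {
  n_t <- length(dets_by_frame)
  if (n_t < 1) stop("need at least one frame")
  tracks <- list()
  next_id <- 1L
  for (j in seq_along(dets_by_frame[[1]])) {
    d <- dets_by_frame[[1]][[j]]
    tracks[[next_id]] <- list(id = next_id,
                              frames = 1L, det_idx = j, last = d)
    next_id <- next_id + 1L
  }
  live <- seq_along(tracks)
  assoc <- vector("list", n_t)
  if (n_t > 1) for (t in seq_len(n_t - 1L)) {
    dets_next <- dets_by_frame[[t + 1L]]
    live <- live[vapply(live, function(i)
      (t + 1L) - max(tracks[[i]]$frames) <= params$occlusion_gap + 1L, TRUE)]
    memo <- new.env(parent = emptyenv())
    smemo <- new.env(parent = emptyenv())
    nr <- length(live); nc <- length(dets_next)
    costs <- matrix(Inf, nr, nc)
    links <- matrix(Inf, nr, nc)
    if (nr > 0 && nc > 0) for (r in seq_len(nr)) {
      i <- live[r]
      tau <- new_track(tracks[[i]]$id,
                       stats::setNames(list(tracks[[i]]$last),
                                       max(tracks[[i]]$frames)))
      ec <- .extension_costs(tau, dets_by_frame, t, params, spacing, memo, smemo)
      costs[r, ] <- ec$edge_costs
      links[r, ] <- ec$link_costs
    }
    m <- match_frame(costs)
    assoc[[t + 1L]] <- list(track_ids = vapply(live, function(i) tracks[[i]]$id,
                                               integer(1)),
                            track_last_frame = vapply(live, function(i)
                              max(tracks[[i]]$frames), integer(1)),
                            link_costs = links, edge_costs = costs)
    if (!is.null(m$matches)) for (k in seq_len(nrow(m$matches))) {
      i <- live[m$matches[k, 1]]; j <- m$matches[k, 2]
      tracks[[i]]$frames <- c(tracks[[i]]$frames, t + 1L)
      tracks[[i]]$det_idx <- c(tracks[[i]]$det_idx, j)
      tracks[[i]]$last <- dets_next[[j]]
    }
    for (j in m$new_detections) {
      tracks[[next_id]] <- list(id = next_id, frames = t + 1L, det_idx = j,
                                last = dets_next[[j]])
      live <- c(live, next_id)
      next_id <- next_id + 1L
    }
  }
  out_tracks <- lapply(tracks, function(tr) {
    dets <- lapply(seq_along(tr$frames), function(k) {
      d <- dets_by_frame[[tr$frames[k]]][[tr$det_idx[k]]]
      d$id <- tr$det_idx[k]
      d
    })
    names(dets) <- tr$frames
    new_track(tr$id, dets)
  })
  structure(list(tracks = out_tracks, assoc = assoc, params = params,
                 spacing = spacing),
            class = "tracking_result")
}
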