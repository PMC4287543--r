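#' A montage tile
#'
#' One overlapping subsection of a larger static specimen: per-channel 3-D
#' arrays plus the microscope stage position recorded at capture.
#'
#' @param id Integer tile id (unique within a tile set).
#' @param volumes List of 3-D arrays (z, y, x), one per channel, equal shapes.
#' @param stage_um Numeric (x, y, z) stage position in micrometres.
#' @param spacing A [voxel_spacing()], shared by all tiles.
#' @param channel_roles Optional character vector of channel roles.
#' @return An object of class `tile`.
#' @export
tile <- function(id, volumes, stage_um, spacing, channel_roles = NULL) {
  if (!is.list(volumes)) volumes <- list(volumes)
  dims <- lapply(volumes, dim)
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("all channels of a tile must share one shape")
  if (length(stage_um) != 3L || any(!is.finite(stage_um)))
    stop("stage_um must be a finite (x, y, z) triple")
  structure(list(id = as.integer(id), volumes = volumes,
                 stage_um = as.numeric(stage_um), spacing = spacing,
                 channel_roles = channel_roles),
            class = "tile")
}

# nominal (x, y, z) voxel offset of a tile's origin in the global frame
.tile_nominal_vox <- function(tl) {
  round(tl$stage_um / c(tl$spacing$dx, tl$spacing$dy, tl$spacing$dz))
}

# per-axis (x, y, z) voxel extents of a tile
.tile_extent_vox <- function(tl) {
  d <- dim(tl$volumes[[1]])
  c(d[3], d[2], d[1])
}

#' Stage-predicted adjacency between tiles
#'
#' Two tiles are candidates for pairwise registration when their
#' stage-predicted bounding boxes overlap and the overlap spans the full
#' tile extent along all but at most one of the x and y axes - i.e. they are
#' neighbours along a single grid axis. Diagonal corner-only contacts are
#' excluded; the stage moves in a checkerboard fashion so grid neighbours
#' carry all the information needed.
#'
#' @param tiles List of [tile()] objects.
#' @return Data frame with columns `a`, `b` (tile ids, a < b).
#' @export
adjacency_from_stage <- function(tiles) {
  n <- length(tiles)
  pos <- t(vapply(tiles, .tile_nominal_vox, numeric(3)))
  ext <- t(vapply(tiles, .tile_extent_vox, numeric(3)))
  ids <- vapply(tiles, function(t) t$id, integer(1))
  pairs <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lo <- pmax(pos[i, ], pos[j, ])
    hi <- pmin(pos[i, ] + ext[i, ], pos[j, ] + ext[j, ])
    ov <- hi - lo
    if (any(ov < 1)) next
    # an axis counts as partially overlapping when clearly less than the full
    # tile extent (80% allows for stage jitter); grid neighbours are partial
    # along exactly one of x, y, diagonal contacts along both
    partial_xy <- sum(ov[1:2] < 0.8 * pmin(ext[i, 1:2], ext[j, 1:2]))
    if (partial_xy > 1) next
    pairs <- rbind(pairs, data.frame(a = min(ids[i], ids[j]),
                                     b = max(ids[i], ids[j])))
  }
  if (is.null(pairs))
    stop("no stage-adjacent tile pairs: the tiles do not overlap, montage impossible")
  pairs[order(pairs$a, pairs$b), , drop = FALSE]
}

#' Normalized covariance of two equally shaped arrays
#'
#' Mean-subtracted, variance-normalized similarity in `[-1, 1]`, invariant
#' to per-image affine intensity changes (gain and offset), used to score
#' candidate tile shifts.
#'
#' @param a,b Numeric arrays of equal shape with at least 2 elements.
#' @return Scalar score in `[-1, 1]`; 0 with a warning when either input is
#'   constant.
#' @export
normalized_covariance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("inputs must have equal shape")
  if (length(a) < 2) stop("need at least 2 voxels")
  da <- a - mean(a); db <- b - mean(b)
  na <- sqrt(sum(da^2)); nb <- sqrt(sum(db^2))
  if (na == 0 || nb == 0) {
    warning("constant input to normalized_covariance; score defined as 0")
    return(0)
  }
  max(min(sum(da * db) / (na * nb), 1), -1)
}

#' Maximum intensity projection
#'
#' @param vol3d 3-D array (z, y, x).
#' @param axis Axis to project along: 1 = z, 2 = y, 3 = x.
#' @return 2-D array of per-pixel maxima.
#' @export
mip <- function(vol3d, axis = 1) {
  stopifnot(length(dim(vol3d)) == 3L, axis %in% 1:3)
  apply(vol3d, setdiff(1:3, axis), max)
}

# overlap of two tile grids for integer (x, y, z) voxel offset `off` of b
# relative to a; returns NULL or list(a = indices, b = indices) per axis (z,y,x)
.overlap_slices <- function(dim_a, dim_b, off_xyz) {
  off_zyx <- off_xyz[c(3, 2, 1)]
  lo <- pmax(0, off_zyx)
  hi <- pmin(dim_a, off_zyx + dim_b)
  if (any(hi <= lo)) return(NULL)
  list(a = lapply(1:3, function(k) (lo[k] + 1):hi[k]),
       b = lapply(1:3, function(k) (lo[k] - off_zyx[k] + 1):(hi[k] - off_zyx[k])))
}

#' Register one stage-adjacent tile pair
#'
#' Two-stage translational search around the stage-predicted offset. Stage
#' one projects both tiles along z (the gravity axis, the only axis with a
#' single subsection) and exhaustively shifts the two maximum-intensity
#' images against each other over `[-window, window]^2` in (x, y), scoring
#' each shift by the normalized covariance of the overlapping regions. Stage
#' two fixes the best (x, y) shift and refines z over `[-window, window]`
#' using the full 3-D overlap volumes. Candidates with fewer than
#' `min_overlap` overlapping voxels are skipped.
#'
#' @param tile_a,tile_b Stage-adjacent [tile()] objects.
#' @param window Search half-width in voxels per axis (default 20).
#' @param channel Index of the structural channel used for registration
#'   (a channel with semi-sparse structure spanning tiles, e.g. vasculature).
#' @param min_overlap Minimum overlapping voxel count for a valid score.
#' @return List of class `pair_offset`: `a`, `b`, `delta` (x, y, z voxels
#'   relative to the stage-predicted offset), `score` (3-D normalized
#'   covariance at the chosen shift; `-Inf` and `flagged = TRUE` if every
#'   candidate was skipped).
#' @export
register_pair <- function(tile_a, tile_b, window = 20, channel = 1,
                          min_overlap = 32) {
  stopifnot(window >= 0)
  off0 <- .tile_nominal_vox(tile_b) - .tile_nominal_vox(tile_a)
  va <- tile_a$volumes[[channel]]; vb <- tile_b$volumes[[channel]]
  ma <- mip(va, 1); mb <- mip(vb, 1)
  best <- list(score = -Inf, dxy = c(0, 0))
  for (dy in -window:window) for (dx in -window:window) {
    off <- off0[1:2] + c(dx, dy)
    lo <- pmax(0, off[c(2, 1)]); hi <- pmin(dim(ma), off[c(2, 1)] + dim(mb))
    if (any(hi <= lo)) next
    if (prod(hi - lo) < min_overlap) next
    sa <- ma[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], drop = FALSE]
    sb <- mb[(lo[1] - off[2] + 1):(hi[1] - off[2]),
             (lo[2] - off[1] + 1):(hi[2] - off[1]), drop = FALSE]
    sc <- suppressWarnings(normalized_covariance(sa, sb))
    if (sc > best$score ||
        (sc == best$score && sum(abs(c(dx, dy))) < sum(abs(best$dxy))))
      best <- list(score = sc, dxy = c(dx, dy))
  }
  if (!is.finite(best$score))
    return(structure(list(a = tile_a$id, b = tile_b$id,
                          delta = c(0, 0, 0), score = -Inf, flagged = TRUE),
                     class = "pair_offset"))
  best_z <- list(score = -Inf, dz = 0)
  for (dz in -window:window) {
    off <- c(off0[1:2] + best$dxy, off0[3] + dz)
    sl <- .overlap_slices(dim(va), dim(vb), off)
    if (is.null(sl)) next
    if (prod(vapply(sl$a, length, 1L)) < min_overlap) next
    sa <- va[sl$a[[1]], sl$a[[2]], sl$a[[3]], drop = FALSE]
    sb <- vb[sl$b[[1]], sl$b[[2]], sl$b[[3]], drop = FALSE]
    sc <- suppressWarnings(normalized_covariance(sa, sb))
    if (sc > best_z$score ||
        (sc == best_z$score && abs(dz) < abs(best_z$dz)))
      best_z <- list(score = sc, dz = dz)
  }
  if (!is.finite(best_z$score))
    return(structure(list(a = tile_a$id, b = tile_b$id,
                          delta = c(0, 0, 0), score = -Inf, flagged = TRUE),
                     class = "pair_offset"))
  structure(list(a = tile_a$id, b = tile_b$id,
                 delta = c(best$dxy, best_z$dz), score = best_z$score,
                 flagged = FALSE),
            class = "pair_offset")
}

#' Maximum spanning tree over pairwise registrations
#'
#' Drops the lowest-scoring registration edges until a maximum-weight
#' spanning tree remains (Kruskal on scores, ties broken by the
#' lexicographic tile-id pair), so each tile's final position is anchored
#' through its most reliable registrations only.
#'
#' @param offsets List of `pair_offset` objects covering a connected graph.
#' @param tile_ids Integer vector of all tile ids.
#' @return The subset of `offsets` forming the tree.
#' @export
build_spanning_tree <- function(offsets, tile_ids) {
  scores <- vapply(offsets, function(e) e$score, numeric(1))
  aa <- vapply(offsets, function(e) e$a, integer(1))
  bb <- vapply(offsets, function(e) e$b, integer(1))
  ord <- order(-scores, aa, bb)
  parent <- stats::setNames(tile_ids, as.character(tile_ids))
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  kept <- list()
  for (k in ord) {
    ra <- find(aa[k]); rb <- find(bb[k])
    if (ra != rb) {
      parent[[as.character(ra)]] <- rb
      kept[[length(kept) + 1L]] <- offsets[[k]]
    }
  }
  roots <- unique(vapply(tile_ids, find, numeric(1)))
  if (length(roots) > 1L) {
    comps <- split(tile_ids, vapply(tile_ids, find, numeric(1)))
    stop("registration graph is disconnected; components: ",
         paste(vapply(comps, function(c) paste0("{", paste(c, collapse = ","), "}"), ""),
               collapse = " "))
  }
  kept
}

#' Accumulate global tile offsets along the spanning tree
#'
#' One tile (the root, lowest id by default) is held stationary at its
#' stage-predicted position; every other tile's global delta is its parent's
#' cumulative delta plus the local registration delta along the tree edge
#' (sign-flipped when the edge is traversed against its stored orientation).
#'
#' @param tree List of `pair_offset` edges forming a spanning tree.
#' @param tile_ids Integer vector of tile ids.
#' @param root Root tile id; default the lowest id.
#' @return Named list: tile id -> (x, y, z) global delta in voxels; the
#'   root's delta is `c(0, 0, 0)`.
#' @export
accumulate_deltas <- function(tree, tile_ids, root = min(tile_ids)) {
  gd <- stats::setNames(vector("list", length(tile_ids)), as.character(tile_ids))
  gd[[as.character(root)]] <- c(0, 0, 0)
  remaining <- tree
  repeat {
    progressed <- FALSE
    keep <- list()
    for (e in remaining) {
      ka <- as.character(e$a); kb <- as.character(e$b)
      if (!is.null(gd[[ka]]) && is.null(gd[[kb]])) {
        gd[[kb]] <- gd[[ka]] + e$delta; progressed <- TRUE
      } else if (!is.null(gd[[kb]]) && is.null(gd[[ka]])) {
        gd[[ka]] <- gd[[kb]] - e$delta; progressed <- TRUE
      } else if (is.null(gd[[ka]]) && is.null(gd[[kb]])) {
        keep[[length(keep) + 1L]] <- e
      }
    }
    remaining <- keep
    if (!progressed) break
  }
  if (any(vapply(gd, is.null, TRUE)))
    stop("spanning tree does not reach every tile from the root")
  gd
}

#' Fuse registered tiles into one volume
#'
#' Places every tile at its stage-predicted position plus its resolved
#' global delta (the same delta is applied to every channel of a tile, since
#' all channels of a subsection are captured together) and resolves overlaps
#' by voxel-wise maximum.
#'
#' @param tiles List of [tile()] objects.
#' @param global_deltas Named list from [accumulate_deltas()].
#' @return A [volume5d()] with one time point and all channels; the new
#'   montage dimensions are in `dim()` of its data and are written to the
#'   sidecar by [save_volume()].
#' @export
fuse <- function(tiles, global_deltas) {
  n_ch <- length(tiles[[1]]$volumes)
  pos <- t(vapply(tiles, function(tl)
    .tile_nominal_vox(tl) + global_deltas[[as.character(tl$id)]], numeric(3)))
  ext <- t(vapply(tiles, .tile_extent_vox, numeric(3)))
  origin <- apply(pos, 2, min)
  span <- apply(pos + ext, 2, max) - origin  # (x, y, z)
  out <- array(0, dim = c(1, n_ch, span[3], span[2], span[1]))
  for (k in seq_along(tiles)) {
    p <- pos[k, ] - origin  # 0-based placement (x, y, z)
    d <- dim(tiles[[k]]$volumes[[1]])
    zi <- (p[3] + 1):(p[3] + d[1]); yi <- (p[2] + 1):(p[2] + d[2])
    xi <- (p[1] + 1):(p[1] + d[3])
    for (ch in seq_len(n_ch))
      out[1, ch, zi, yi, xi] <- pmax(out[1, ch, zi, yi, xi],
                                     tiles[[k]]$volumes[[ch]])
  }
  volume5d(out, tiles[[1]]$spacing,
           channel_roles = tiles[[1]]$channel_roles)
}

#' Register and fuse a full tile set
#'
#' Runs the whole montage pipeline: stage-predicted adjacency, pairwise
#' two-stage registration on the structural channel, maximum spanning tree,
#' global delta accumulation, and fusion.
#'
#' @param tiles List of [tile()] objects.
#' @param window Search half-width in voxels (default 20).
#' @param channel Registration channel index.
#' @param root Root tile id (default lowest).
#' @return List: `volume` (fused [volume5d()]), `report` (edges with scores
#'   and deltas, tree membership, global deltas).
#' @export
register_montage <- function(tiles, window = 20, channel = 1,
                             root = min(vapply(tiles, function(t) t$id, integer(1)))) {
  ids <- vapply(tiles, function(t) t$id, integer(1))
  by_id <- stats::setNames(tiles, as.character(ids))
  pairs <- adjacency_from_stage(tiles)
  offsets <- lapply(seq_len(nrow(pairs)), function(k)
    register_pair(by_id[[as.character(pairs$a[k])]],
                  by_id[[as.character(pairs$b[k])]],
                  window = window, channel = channel))
  tree <- build_spanning_tree(offsets, ids)
  gd <- accumulate_deltas(tree, ids, root = root)
  in_tree <- paste(vapply(tree, function(e) e$a, integer(1)),
                   vapply(tree, function(e) e$b, integer(1)))
  report <- list(
    edges = lapply(offsets, function(e)
      list(a = e$a, b = e$b, delta = e$delta, score = e$score,
           in_tree = paste(e$a, e$b) %in% in_tree)),
    root = root,
    global_deltas = gd)
  list(volume = fuse(tiles, gd), report = report)
}
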