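# Incremental 3-D convex hull on physical voxel coordinates. Point counts per
# detection are small (hundreds to a few thousand), so the O(n * faces)
# incremental construction is ample; QHull-style conflict lists are not needed.

.face_normal <- function(pts, f) {
  a <- pts[f[1], ]; b <- pts[f[2], ]; c <- pts[f[3], ]
  u <- b - a; v <- c - a
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.hull_incremental <- function(pts, eps) {
  n <- nrow(pts)
  # initial extremes: most distant pair along x, then from the line, then plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) return(NULL)
  dir <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  t_ <- rel %*% dir / sum(dir^2)
  perp <- rel - outer(as.numeric(t_), dir)
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) <= eps) return(NULL)
  nrm <- .face_normal(pts, c(i1, i2, i3))
  h <- rel %*% nrm
  i4 <- which.max(abs(h))
  if (abs(h[i4]) <= eps * sqrt(sum(nrm^2))) return(NULL)
  faces <- rbind(c(i1, i2, i3), c(i1, i3, i4), c(i1, i4, i2), c(i2, i4, i3))
  # orient all faces outward w.r.t. the tetrahedron centroid
  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  for (k in seq_len(nrow(faces))) {
    nf <- .face_normal(pts, faces[k, ])
    if (sum(nf * (centroid - pts[faces[k, 1], ])) > 0)
      faces[k, ] <- faces[k, c(1, 3, 2)]
  }
  face_geom <- function(fs) {
    nrm <- t(apply(fs, 1, function(f) .face_normal(pts, f)))
    list(n = nrm,
         off = rowSums(nrm * pts[fs[, 1], , drop = FALSE]),
         len = sqrt(rowSums(nrm^2)))
  }
  geom <- face_geom(faces)
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- as.numeric(geom$n %*% pts[p, ]) - geom$off > eps * geom$len
    if (!any(vis)) next
    vf <- faces[vis, , drop = FALSE]
    dir_edges <- rbind(vf[, 1:2], vf[, 2:3], vf[, c(3, 1)])
    keys <- paste(dir_edges[, 1], dir_edges[, 2])
    rev_keys <- paste(dir_edges[, 2], dir_edges[, 1])
    horizon <- dir_edges[!(rev_keys %in% keys), , drop = FALSE]
    new_faces <- cbind(horizon, p)
    faces <- rbind(faces[!vis, , drop = FALSE], new_faces)
    ng <- face_geom(new_faces)
    geom <- list(n = rbind(geom$n[!vis, , drop = FALSE], ng$n),
                 off = c(geom$off[!vis], ng$off),
                 len = c(geom$len[!vis], ng$len))
  }
  faces
}

#' Convex hull mesh of a detection
#'
#' Watertight triangular mesh (outward-oriented facets) of a detection's
#' voxel centers in physical micrometres, as rendered around each cell.
#' Degenerate voxel sets (fewer than four points, collinear or coplanar,
#' e.g. one-voxel-thick detections) fall back to an axis-aligned bounding
#' box mesh and are flagged rather than failing the pipeline.
#'
#' @param det A [detection()], or an n x 3 matrix of (x, y, z) points in
#'   micrometres.
#' @param spacing A [voxel_spacing()] (needed when `det` is a detection).
#' @return List of class `hull_mesh`: `vertices` (m x 3, x/y/z um), `faces`
#'   (k x 3 vertex indices, outward orientation), `degenerate` flag.
#' @export
convex_hull <- function(det, spacing = NULL) {
  pts <- if (inherits(det, "detection")) {
    stopifnot(!is.null(spacing))
    # only per-(x,y)-column z-extremes can be hull vertices; interior column
    # voxels are convex combinations of the extremes
    v <- det$voxels
    col <- paste(v[, 2], v[, 3])
    keep <- unlist(lapply(split(seq_len(nrow(v)), col), function(i)
      i[c(which.min(v[i, 1]), which.max(v[i, 1]))]), use.names = FALSE)
    voxel_coords_um(v[unique(keep), , drop = FALSE], spacing)
  } else as.matrix(det)
  pts <- unique(round(pts, 12))
  dimnames(pts) <- NULL
  eps <- 1e-9 * max(1, max(abs(pts)))
  faces <- if (nrow(pts) >= 4) .hull_incremental(pts, eps) else NULL
  if (is.null(faces)) {
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    hi <- pmax(hi, lo + 1e-9)
    corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                     z = c(lo[3], hi[3])))
    faces <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                   c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                   c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
    return(structure(list(vertices = corners, faces = faces, degenerate = TRUE),
                     class = "hull_mesh"))
  }
  used <- sort(unique(as.integer(faces)))
  remap <- match(faces, used)
  structure(list(vertices = pts[used, , drop = FALSE],
                 faces = matrix(remap, ncol = 3),
                 degenerate = FALSE),
            class = "hull_mesh")
}

#' Signed volume of a hull mesh
#'
#' Divergence-theorem volume of an outward-oriented triangular mesh, in
#' cubic micrometres.
#'
#' @param mesh A `hull_mesh`.
#' @return Scalar volume.
#' @export
hull_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  tot <- 0
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c <- v[f[k, 3], ]
    tot <- tot + (a[1] * (b[2] * c[3] - b[3] * c[2]) -
                  a[2] * (b[1] * c[3] - b[3] * c[1]) +
                  a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
  }
  abs(tot)
}

#' Test points against a hull mesh
#'
#' Half-space containment: TRUE for points on or inside every facet plane
#' (within a small tolerance).
#'
#' @param mesh A `hull_mesh`.
#' @param pts n x 3 matrix of (x, y, z) points.
#' @param tol Planar tolerance in micrometres.
#' @return Logical vector of length n.
#' @export
hull_contains <- function(mesh, pts, tol = 1e-7) {
  pts <- rbind(pts)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    nf <- .face_normal(mesh$vertices, f)
    nn <- sqrt(sum(nf^2))
    if (nn == 0) next
    d <- (sweep(pts, 2, mesh$vertices[f[1], ]) %*% nf) / nn
    inside <- inside & (d <= tol + 1e-9 * max(abs(mesh$vertices)))
  }
  inside
}

#' Export hull meshes as Wavefront OBJ
#'
#' Vertices are written in micrometres; one named object per detection.
#'
#' @param detections List of [detection()]s carrying `hull` meshes.
#' @param path Output path.
#' @export
export_hulls_obj <- function(detections, path) {
  con <- file(path, "w")
  on.exit(close(con))
  offset <- 0L
  for (det in detections) {
    if (is.null(det$hull)) next
    writeLines(sprintf("o detection_%s_frame_%d", det$id, det$frame), con)
    v <- det$hull$vertices
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    f <- det$hull$faces + offset
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    offset <- offset + nrow(v)
  }
  invisible(NULL)
}
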