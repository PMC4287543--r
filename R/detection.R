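#' A segmented cell in one frame
#'
#' One connected component of foreground voxels in one frame, treated as one
#' cell. Voxel indices are 1-based (z, y, x); derived physical quantities are
#' computed from the voxel spacing at construction.
#'
#' @param frame Frame index (1-based).
#' @param voxels Integer matrix with columns (z, y, x), one row per voxel.
#' @param spacing A [voxel_spacing()].
#' @param id Optional integer detection id.
#' @return An object of class `detection` with fields `frame`, `voxels`,
#'   `voxel_count`, `centroid_um` (x, y, z), `volume_um3`, optional `hull`.
#' @export
detection <- function(frame, voxels, spacing, id = NULL) {
  voxels <- matrix(as.integer(rbind(voxels)), ncol = 3)
  colnames(voxels) <- c("z", "y", "x")
  if (nrow(voxels) == 0L) stop("a detection must contain at least one voxel")
  coords <- voxel_coords_um(voxels, spacing)
  structure(list(
    frame = as.integer(frame),
    id = if (is.null(id)) NA_integer_ else as.integer(id),
    voxels = voxels,
    voxel_count = nrow(voxels),
    centroid_um = colMeans(coords),
    volume_um3 = nrow(voxels) * spacing$dx * spacing$dy * spacing$dz,
    hull = NULL
  ), class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("detection %s @ frame %d: %d voxels, %.2f um^3, centroid (%.1f, %.1f, %.1f) um\n",
              ifelse(is.na(x$id), "<unassigned>", x$id), x$frame,
              x$voxel_count, x$volume_um3,
              x$centroid_um[1], x$centroid_um[2], x$centroid_um[3]))
  invisible(x)
}

# linear scan-order key of a detection's first voxel (z fastest), used for
# deterministic ordering of detection lists
.det_order_key <- function(det, dims) {
  v <- det$voxels
  min((v[, 1] - 1) + dims[1] * ((v[, 2] - 1) + dims[2] * (v[, 3] - 1)))
}
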