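#' Physical voxel spacing
#'
#' Spacing of the voxel grid in micrometres per voxel along x, y and z.
#' Confocal stacks are typically anisotropic (z step coarser than the xy
#' pixel pitch), so every distance computed by this package is taken in
#' physical micrometres through this object.
#'
#' @param dx,dy,dz Micrometres per voxel along x, y, z. All strictly positive.
#' @return An object of class `voxel_spacing`.
#' @examples
#' voxel_spacing(0.8, 0.8, 1)
#' @export
voxel_spacing <- function(dx, dy, dz) {
  vals <- c(dx = dx, dy = dy, dz = dz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("voxel spacing must be finite and strictly positive in all of x, y, z")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz)),
            class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx=%g dy=%g dz=%g um/voxel\n", x$dx, x$dy, x$dz))
  invisible(x)
}

#' Physical coordinates of voxel indices
#'
#' Converts 1-based voxel indices (z, y, x) into physical (x, y, z)
#' coordinates in micrometres, placing voxel (1,1,1) at the origin. This is
#' the single conversion point used everywhere distances are computed.
#'
#' @param voxels Integer matrix with columns (z, y, x), one row per voxel.
#' @param spacing A [voxel_spacing()].
#' @return Numeric matrix with columns (x, y, z) in micrometres.
#' @export
voxel_coords_um <- function(voxels, spacing) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  voxels <- rbind(voxels)
  cbind(x = (voxels[, 3] - 1) * spacing$dx,
        y = (voxels[, 2] - 1) * spacing$dy,
        z = (voxels[, 1] - 1) * spacing$dz)
}

#' 5-D microscopy volume
#'
#' Container for a 5-D (t, channel, z, y, x) intensity array with its
#' physical calibration. Exactly the layout used throughout the pipeline:
#' time first, then channel, then the three spatial axes in (z, y, x) array
#' order with physical coordinates reported as (x, y, z) micrometres.
#'
#' @param data 5-D numeric array ordered (t, channel, z, y, x), non-negative.
#' @param spacing A [voxel_spacing()].
#' @param frame_interval_min Minutes between consecutive frames.
#' @param channel_roles Character vector, one entry per channel, each one of
#'   `"cell"`, `"vessel"`, `"other"`. For the tracking pipeline exactly one
#'   channel must be `"cell"` and at most one `"vessel"`.
#' @return An object of class `volume5d`.
#' @export
volume5d <- function(data, spacing, frame_interval_min = 20,
                     channel_roles = NULL) {
  if (length(dim(data)) != 5L)
    stop("`data` must be a 5-D array ordered (t, channel, z, y, x)")
  if (any(dim(data) < 1L)) stop("all axes of `data` must have length >= 1")
  if (any(data < 0)) stop("intensities must be non-negative")
  stopifnot(inherits(spacing, "voxel_spacing"))
  n_ch <- dim(data)[2]
  if (is.null(channel_roles)) channel_roles <- rep("other", n_ch)
  if (length(channel_roles) != n_ch ||
      !all(channel_roles %in% c("cell", "vessel", "other")))
    stop("`channel_roles` must give one of cell/vessel/other per channel")
  if (sum(channel_roles == "cell") > 1 || sum(channel_roles == "vessel") > 1)
    stop("at most one channel may be flagged 'cell' and one 'vessel'")
  structure(list(data = data, spacing = spacing,
                 frame_interval_min = as.numeric(frame_interval_min),
                 channel_roles = channel_roles),
            class = "volume5d")
}

#' @export
print.volume5d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume5d: %d frame(s), %d channel(s), %dx%dx%d (z,y,x) voxels\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  roles: %s; frame interval %g min; ",
              paste(x$channel_roles, collapse = ", "), x$frame_interval_min))
  print(x$spacing)
  invisible(x)
}

#' Extract one 3-D frame/channel from a 5-D volume
#'
#' @param vol A [volume5d()].
#' @param t Frame index (1-based).
#' @param channel Channel index, or a role name (`"cell"`/`"vessel"`).
#' @return 3-D array ordered (z, y, x).
#' @export
get_frame <- function(vol, t, channel) {
  stopifnot(inherits(vol, "volume5d"))
  if (is.character(channel)) {
    idx <- which(vol$channel_roles == channel)
    if (length(idx) != 1L)
      stop("no unique channel with role '", channel, "'")
    channel <- idx
  }
  d <- dim(vol$data)
  if (t < 1 || t > d[1]) stop("frame index out of range")
  array(vol$data[t, channel, , , ], dim = d[3:5])
}
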