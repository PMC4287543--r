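#' Otsu threshold of a 3-D image
#'
#' Picks the histogram threshold maximizing the between-class variance over
#' a 256-bin intensity histogram; foreground is every voxel strictly above
#' the threshold.
#'
#' @param vol3d Numeric array with at least two distinct values. A constant
#'   image yields an all-background mask with a warning.
#' @param nbins Number of histogram bins (default 256).
#' @return Logical array of the same shape (foreground mask) with attribute
#'   `threshold`.
#' @export
otsu_threshold <- function(vol3d, nbins = 256) {
  v <- as.numeric(vol3d)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant image: Otsu threshold undefined, returning empty foreground")
    out <- array(FALSE, dim = dim(vol3d))
    attr(out, "threshold") <- rng[1]
    return(out)
  }
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins),
                     nbins)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[nbins]; mtot <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1)
  bcv[valid] <- (mtot * w0[valid] - n * m0[valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  k <- which.max(bcv)
  thr <- edges[k + 1]
  out <- array(v > thr, dim = dim(vol3d))
  attr(out, "threshold") <- thr
  out
}

# (z,y,x) integer offsets of an anisotropy-aware ball of physical radius r um
.ball_offsets <- function(radius_um, spacing) {
  s <- c(spacing$dz, spacing$dy, spacing$dx)
  rv <- floor(radius_um / s)
  g <- as.matrix(expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3]))
  keep <- (g[, 1] * s[1])^2 + (g[, 2] * s[2])^2 + (g[, 3] * s[3])^2 <= radius_um^2
  g[keep, , drop = FALSE]
}

# shift a logical array by (dz,dy,dx), filling exposed borders with `fill`
.shift_mask <- function(mask, by, fill) {
  d <- dim(mask)
  out <- array(fill, dim = d)
  src <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - by[k]
    i[i >= 1 & i <= d[k]]
  })
  dst <- lapply(1:3, function(k) src[[k]] + by[k])
  if (any(vapply(src, length, 1L) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Morphological closing with a physical-radius ball
#'
#' Dilation followed by erosion with a binary ball structuring element whose
#' radius is given in micrometres and converted per axis to voxels (so the
#' element is anisotropy-aware). Outside-image voxels count as foreground
#' during erosion, which guarantees the closing never removes input
#' foreground. Used to fill erroneous holes left by thresholding.
#'
#' @param binvol Logical 3-D array.
#' @param radius_um Ball radius in micrometres (> 0), default 1.
#' @param spacing A [voxel_spacing()].
#' @return Logical array containing the input.
#' @export
close_binary <- function(binvol, radius_um = 1, spacing) {
  stopifnot(radius_um > 0)
  offs <- .ball_offsets(radius_um, spacing)
  dil <- array(FALSE, dim = dim(binvol))
  for (k in seq_len(nrow(offs)))
    dil <- dil | .shift_mask(binvol, offs[k, ], FALSE)
  ero <- array(TRUE, dim = dim(binvol))
  for (k in seq_len(nrow(offs)))
    ero <- ero & .shift_mask(dil, -offs[k, ], TRUE)
  ero
}

#' Segmentation parameters
#'
#' @param min_volume_um3 Smallest physical volume a connected component may
#'   have; components strictly below it are discarded as noise. Default 19
#'   cubic micrometres (a value below the smallest expected cell soma;
#'   cell-type dependent and user-settable).
#' @param closing_radius_um Ball radius for [close_binary()], default 1.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_volume_um3 = 19, closing_radius_um = 1) {
  if (min_volume_um3 <= 0 || closing_radius_um <= 0)
    stop("segmentation parameters must be positive")
  structure(list(min_volume_um3 = min_volume_um3,
                 closing_radius_um = closing_radius_um),
            class = "segmentation_params")
}

#' Extract detections from a binary frame
#'
#' Labels the 26-connected components of the foreground, discards components
#' whose physical volume is strictly below the minimum (components exactly
#' at the threshold are kept), and returns one [detection()] per surviving
#' component with centroid and volume in micrometres. Detections are ordered
#' by the scan-order position of each component's first voxel, so the output
#' is deterministic.
#'
#' @param binvol Logical 3-D array.
#' @param spacing A [voxel_spacing()].
#' @param params A [segmentation_params()].
#' @param frame Frame index stored on the detections.
#' @return List of [detection()] objects (possibly empty).
#' @export
extract_detections <- function(binvol, spacing, params = segmentation_params(),
                               frame = 1L) {
  d <- dim(binvol)
  lab <- cpp_label26(as.logical(binvol), as.integer(d))
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  idx <- which(lab > 0)
  groups <- split(idx, lab[idx])
  vox_vol <- spacing$dx * spacing$dy * spacing$dz
  dets <- list()
  for (g in groups[order(as.integer(names(groups)))]) {
    if (length(g) * vox_vol < params$min_volume_um3) next
    zz <- (g - 1) %% d[1] + 1
    yy <- ((g - 1) %/% d[1]) %% d[2] + 1
    xx <- (g - 1) %/% (d[1] * d[2]) + 1
    dets[[length(dets) + 1L]] <- detection(frame, cbind(zz, yy, xx), spacing)
  }
  for (k in seq_along(dets)) dets[[k]]$id <- k
  dets
}

#' Anisotropy-aware vessel distance map
#'
#' Exact Euclidean distance (micrometres) from every voxel to the nearest
#' vessel-foreground voxel, computed with a separable distance transform that
#' respects unequal axis spacing. Zero exactly on the foreground.
#'
#' @param vessel_binvol Logical 3-D array of vessel foreground. An empty
#'   foreground returns an all-infinite map with a warning.
#' @param spacing A [voxel_spacing()].
#' @return Numeric 3-D array of distances in micrometres.
#' @export
vessel_distance_map <- function(vessel_binvol, spacing) {
  d <- dim(vessel_binvol)
  if (!any(vessel_binvol)) {
    warning("empty vessel foreground: distance map is infinite everywhere")
    return(array(Inf, dim = d))
  }
  array(cpp_edt3d(as.logical(vessel_binvol), as.integer(d),
                  spacing$dz, spacing$dy, spacing$dx), dim = d)
}

#' Segment a 5-D movie
#'
#' Per frame: the cell channel is (optionally) denoised, Otsu-thresholded,
#' morphologically closed and split into detections; the vessel channel is
#' (optionally) denoised, thresholded, closed and turned into a distance
#' map. The Otsu threshold adapts per frame and channel.
#'
#' @param vol A [volume5d()] with designated cell (and, for distance maps,
#'   vessel) channels.
#' @param params A [segmentation_params()].
#' @param denoise Run the channel-specific denoisers first (default TRUE).
#' @param hulls Attach convex hull meshes to detections (default TRUE).
#' @param cell_denoise,vessel_denoise Parameter objects for the denoisers.
#' @return List: `detections` (per-frame list of [detection()] lists),
#'   `distance_maps` (per-frame list or NULL if no vessel channel),
#'   `thresholds` (per-frame cell-channel Otsu thresholds).
#' @export
segment_movie <- function(vol, params = segmentation_params(), denoise = TRUE,
                          hulls = TRUE,
                          cell_denoise = cell_denoise_params(),
                          vessel_denoise = vessel_denoise_params()) {
  stopifnot(inherits(vol, "volume5d"))
  n_t <- dim(vol$data)[1]
  has_vessel <- any(vol$channel_roles == "vessel")
  detections <- vector("list", n_t)
  dmaps <- if (has_vessel) vector("list", n_t) else NULL
  thresholds <- numeric(n_t)
  for (t in seq_len(n_t)) {
    cellv <- get_frame(vol, t, "cell")
    if (denoise) cellv <- denoise_cell_channel(cellv, cell_denoise)
    mask <- suppressWarnings(otsu_threshold(cellv))
    thresholds[t] <- attr(mask, "threshold")
    mask <- close_binary(mask, params$closing_radius_um, vol$spacing)
    dets <- extract_detections(mask, vol$spacing, params, frame = t)
    if (hulls)
      dets <- lapply(dets, function(det) {
        det$hull <- convex_hull(det, vol$spacing)
        det
      })
    detections[[t]] <- dets
    if (has_vessel) {
      vesv <- get_frame(vol, t, "vessel")
      if (denoise) vesv <- denoise_vessel_channel(vesv, vessel_denoise)
      vmask <- suppressWarnings(otsu_threshold(vesv))
      vmask <- close_binary(vmask, params$closing_radius_um, vol$spacing)
      dmaps[[t]] <- suppressWarnings(vessel_distance_map(vmask, vol$spacing))
    }
  }
  list(detections = detections, distance_maps = dmaps, thresholds = thresholds)
}
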