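#' Estimate the low-frequency background of a 3-D image
#'
#' Fluorescence stacks are modelled as true signal plus a slowly varying
#' background plus shot noise. The background component is estimated with a
#' separable Gaussian low-pass whose window is given in voxels per axis; the
#' Gaussian sigma is `neighborhood / 6` with the kernel truncated at three
#' sigma, and borders are handled by reflection.
#'
#' @param vol3d 3-D numeric array (z, y, x).
#' @param neighborhood Window size in voxels per axis; default 100, useful
#'   range roughly 75-250. Values above four times the largest image
#'   dimension are clamped with a warning.
#' @return 3-D array of the same shape: the estimated background.
#' @export
estimate_background <- function(vol3d, neighborhood = 100) {
  d <- dim(vol3d)
  stopifnot(length(d) == 3L)
  if (neighborhood < 3) stop("`neighborhood` must be >= 3 voxels")
  cap <- 4 * max(d)
  if (neighborhood > cap) {
    warning("neighborhood ", neighborhood, " larger than 4x max image dimension; clamped to ", cap)
    neighborhood <- cap
  }
  sigma <- neighborhood / 6
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- cpp_conv1d_axis(as.numeric(vol3d), as.integer(d), 1L, k)
  out <- cpp_conv1d_axis(out, as.integer(d), 2L, k)
  cpp_conv1d_axis(out, as.integer(d), 3L, k)
}

#' Parameters for cell-channel denoising
#'
#' @param background_neighborhood Gaussian window in voxels (default 100).
#' @param median_radius Median filter radius in voxels; radius 1 gives the
#'   3x3x3 window used throughout.
#' @return A list of class `cell_denoise_params`.
#' @export
cell_denoise_params <- function(background_neighborhood = 100, median_radius = 1) {
  if (background_neighborhood < 3) stop("background_neighborhood must be >= 3")
  if (median_radius != 1) stop("only median_radius = 1 (3x3x3 window) is supported")
  structure(list(background_neighborhood = background_neighborhood,
                 median_radius = median_radius),
            class = "cell_denoise_params")
}

#' Denoise the cell channel
#'
#' Subtracts the Gaussian-estimated low-frequency background, clamps
#' negative residuals to zero (intensities are physical), then removes
#' high-frequency shot noise with a 3x3x3 median filter. The foreground of
#' the cell channel sits in small high-frequency regions (cell somata), which
#' survive the subtraction while slow illumination gradients are removed.
#'
#' @param vol3d 3-D numeric array.
#' @param params A [cell_denoise_params()].
#' @return Denoised 3-D array, non-negative, same shape.
#' @export
denoise_cell_channel <- function(vol3d, params = cell_denoise_params()) {
  d <- dim(vol3d)
  bg <- estimate_background(vol3d, params$background_neighborhood)
  resid <- pmax(vol3d - bg, 0)
  out <- cpp_median3(as.numeric(resid), as.integer(d))
  array(out, dim = d)
}

#' Global noise-variance estimate from the Laplacian response
#'
#' Convolves the image with the 3-D 6-neighbour Laplacian (center -6,
#' face-neighbours +1) and returns the response variance divided by the sum
#' of squared kernel coefficients (42), which makes the estimator unbiased
#' for i.i.d. zero-mean noise: any smooth underlying structure has a
#' near-zero Laplacian and contributes little. Only interior voxels (one
#' voxel margin) enter the variance.
#'
#' @param vol3d 3-D numeric array, at least 3 voxels per axis.
#' @return Non-negative scalar: estimated noise variance (intensity^2).
#' @export
estimate_noise_variance <- function(vol3d) {
  d <- dim(vol3d)
  stopifnot(length(d) == 3L)
  if (any(d < 3)) stop("need at least 3 voxels per axis")
  a <- vol3d
  lap <- -6 * a
  lap <- lap + .shift3(a, c( 1, 0, 0)) + .shift3(a, c(-1, 0, 0)) +
               .shift3(a, c(0,  1, 0)) + .shift3(a, c(0, -1, 0)) +
               .shift3(a, c(0, 0,  1)) + .shift3(a, c(0, 0, -1))
  interior <- lap[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  v <- mean(interior^2) - mean(interior)^2
  max(v / 42, 0)
}

# shift a 3-D array by (dz,dy,dx) with edge replication
.shift3 <- function(a, by) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) pmin(pmax(seq_len(d[k]) - by[k], 1L), d[k]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Minimum gap of the intensity histogram
#'
#' The smallest absolute difference between two distinct occupied intensity
#' values of the image: the step size used by each vessel-denoising sweep.
#'
#' @param vol3d Numeric array with at least two distinct values.
#' @return Scalar gap in intensity units.
#' @export
histogram_min_gap <- function(vol3d) {
  v <- sort(unique(as.numeric(vol3d)))
  if (length(v) < 2L)
    stop("image has a single intensity value; no histogram gap exists")
  min(diff(v))
}

#' Parameters for vessel-channel denoising
#'
#' @param max_iterations Safety cap on smoothing sweeps (default 500).
#' @return A list of class `vessel_denoise_params`.
#' @export
vessel_denoise_params <- function(max_iterations = 500) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(max_iterations = as.integer(max_iterations)),
            class = "vessel_denoise_params")
}

#' Denoise the vessel channel by iterative histogram-step smoothing
#'
#' The vasculature channel has large dense foreground regions, so instead of
#' background subtraction it is smoothed with an iterative Markov-random-field
#' style scheme: each sweep recomputes the minimum histogram gap `delta` of
#' the current image and moves every voxel by exactly `+delta` or `-delta`
#' toward its 6-neighbourhood mean (voxels already within `delta/2` of the
#' mean do not move). Sweeps stop at the first n where the mean squared
#' difference between the current and original image reaches the noise
#' variance estimated by [estimate_noise_variance()] - i.e. when the image
#' has changed by as much as the noise model predicts - or at the iteration
#' cap.
#'
#' @param vol3d 3-D numeric array. A constant image is returned unchanged.
#' @param params A [vessel_denoise_params()].
#' @param verbose If TRUE, prints per-sweep mean squared difference and delta.
#' @return Denoised 3-D array with attributes `iterations` and `msd`.
#' @export
denoise_vessel_channel <- function(vol3d, params = vessel_denoise_params(),
                                   verbose = FALSE) {
  d <- dim(vol3d)
  stopifnot(length(d) == 3L)
  if (length(unique(as.numeric(vol3d))) < 2L) {
    out <- vol3d
    attr(out, "iterations") <- 0L
    attr(out, "msd") <- 0
    return(out)
  }
  sigma2 <- estimate_noise_variance(vol3d)
  cur <- vol3d
  msd <- 0
  it <- 0L
  while (it < params$max_iterations && msd < sigma2) {
    delta <- tryCatch(histogram_min_gap(cur), error = function(e) 0)
    if (delta <= 0) break
    nb_mean <- (.shift3(cur, c(1, 0, 0)) + .shift3(cur, c(-1, 0, 0)) +
                .shift3(cur, c(0, 1, 0)) + .shift3(cur, c(0, -1, 0)) +
                .shift3(cur, c(0, 0, 1)) + .shift3(cur, c(0, 0, -1))) / 6
    diffm <- nb_mean - cur
    step <- ifelse(abs(diffm) > delta / 2, sign(diffm) * delta, 0)
    if (all(step == 0)) break  # fixed point: no voxel wants to move
    cur <- cur + step
    it <- it + 1L
    msd <- mean((cur - vol3d)^2)
    if (verbose)
      message(sprintf("sweep %d: delta=%g msd=%.4f (target %.4f)", it, delta, msd, sigma2))
  }
  attr(cur, "iterations") <- it
  attr(cur, "msd") <- msd
  cur
}
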