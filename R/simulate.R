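#' Noise model for synthetic movies
#'
#' Additive low-frequency background (smooth cosine field), i.i.d. Gaussian
#' read noise, and salt-type shot noise, mirroring the background + shot
#' decomposition the denoisers assume. Rendered intensities are quantized to
#' integers and clamped at zero, like microscope output.
#'
#' @param background_amp Amplitude of the smooth background field.
#' @param background_scale Length scale (um) of the background variation.
#' @param gaussian_sd Standard deviation of the Gaussian noise.
#' @param salt_prob Per-voxel probability of a salt impulse.
#' @param salt_amp Amplitude of a salt impulse.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(background_amp = 20, background_scale = 40,
                        gaussian_sd = 8, salt_prob = 1e-3, salt_amp = 200) {
  vals <- c(background_amp, background_scale, gaussian_sd, salt_prob, salt_amp)
  if (any(vals < 0)) stop("noise model parameters must be non-negative")
  structure(list(background_amp = background_amp,
                 background_scale = background_scale,
                 gaussian_sd = gaussian_sd,
                 salt_prob = salt_prob, salt_amp = salt_amp),
            class = "noise_model")
}

#' Random clone plan
#'
#' Generates birth/death times, centroid random walks, radii and division
#' events for a small clone of ellipsoidal cells plus two tube-like vessel
#' segments. Per-frame displacements are capped so consecutive ground-truth
#' masks of one cell overlap well above 50%, and distinct cells steer away
#' from each other below a minimum separation so identities stay
#' unambiguous. Daughters are born one frame after the parent ends, placed
#' symmetrically about the parent's last position with slightly smaller
#' radii.
#'
#' @param n_frames Number of frames (>= 6 when divisions are scheduled).
#' @param shape (z, y, x) voxel counts of the volume.
#' @param spacing A [voxel_spacing()].
#' @param seed Integer seed.
#' @param n_founders Founder cell count (default 2).
#' @param n_divisions Number of division events to schedule (default 1;
#'   at most one per founder).
#' @param radii_um Range of ellipsoid semi-axes (default 2.5-4 um; the
#'   smallest axis is assigned to z, matching flattened somata in thin
#'   stacks).
#' @param max_step_um Per-frame centroid displacement cap (default 1).
#' @param min_separation_um Distance below which distinct cells steer apart.
#' @param intensity Peak cell intensity (default 120).
#' @return A list of class `clone_plan`.
#' @export
random_clone_plan <- function(n_frames, shape, spacing, seed,
                              n_founders = 2, n_divisions = 1,
                              radii_um = c(2.5, 4), max_step_um = 1,
                              min_separation_um = 10, intensity = 120) {
  set.seed(seed)
  extent <- c((shape[3] - 1) * spacing$dx, (shape[2] - 1) * spacing$dy,
              (shape[1] - 1) * spacing$dz)  # (x, y, z) um
  margin <- max(radii_um) + 1
  lo <- rep(margin, 3); hi <- pmax(extent - margin, lo + 1)
  cells <- list()
  spawn <- function(id, birth, end, parent, radii) {
    path <- matrix(NA_real_, n_frames, 3)
    list(id = as.integer(id), birth = as.integer(birth), end = as.integer(end),
         parent = parent, path = path, radii = radii,
         intensity = intensity, disp = c(0, 0, 0))
  }
  draw_radii <- function(scale = 1) {
    r <- sort(stats::runif(3, radii_um[1], radii_um[2]), decreasing = TRUE)
    r * scale  # (x, y, z): smallest axis along z
  }
  for (k in seq_len(n_founders)) {
    repeat {
      pos <- stats::runif(3, lo, hi)
      clear <- all(vapply(cells, function(c2)
        sqrt(sum((pos - c2$path[1, ])^2)) >= min_separation_um + 6, TRUE))
      if (clear) break
    }
    cl <- spawn(length(cells) + 1L, 1L, n_frames, NA_integer_, draw_radii())
    cl$path[1, ] <- pos
    cells[[cl$id]] <- cl
  }
  n_divisions <- min(n_divisions, n_founders)
  if (n_divisions > 0) {
    if (n_frames < 6) stop("need >= 6 frames to schedule a division")
    div_frames <- sort(sample(3:(n_frames - 3), n_divisions))
    dividers <- sort(sample(seq_len(n_founders), n_divisions))
    for (k in seq_len(n_divisions)) {
      p <- dividers[k]; f <- div_frames[k]
      cells[[p]]$end <- as.integer(f)
      dir <- stats::rnorm(3); dir[3] <- dir[3] * 0.3
      dir <- dir / sqrt(sum(dir^2))
      for (s in c(-1, 1)) {
        cl <- spawn(length(cells) + 1L, f + 1L, n_frames, cells[[p]]$id,
                    draw_radii(0.8))
        cl$disp <- s * dir * mean(cells[[p]]$radii) * 1.25
        cells[[cl$id]] <- cl
      }
    }
  }
  # walk the paths frame by frame, steering apart below the separation bound
  for (f in seq_len(n_frames)) {
    for (k in seq_along(cells)) {
      cl <- cells[[k]]
      if (f < cl$birth || f > cl$end) next
      if (f == cl$birth) {
        if (!is.na(cl$parent) && any(is.na(cl$path[f, ]))) {
          # place both daughters jointly: pick the cleavage direction that
          # best preserves separation after clamping to the volume bounds
          sib <- which(vapply(cells, function(c2)
            identical(c2$parent, cl$parent) && c2$birth == cl$birth, TRUE))
          pp <- cells[[cl$parent]]
          origin <- pp$path[pp$end, ]
          mag <- mean(pp$radii) * 1.25
          others <- NULL
          for (m in seq_along(cells)) {
            if (m %in% sib) next
            om <- cells[[m]]
            if (f >= om$birth && f <= om$end && !any(is.na(om$path[max(f - 1L, 1L), ])))
              others <- rbind(others, om$path[max(f - 1L, 1L), ])
          }
          dirs <- rbind(cl$disp / sqrt(sum(cl$disp^2)),
                        c(1, 0, 0), c(0, 1, 0),
                        c(1, 1, 0) / sqrt(2), c(1, -1, 0) / sqrt(2))
          best <- NULL; best_score <- -Inf
          for (r in seq_len(nrow(dirs))) {
            pa <- pmin(pmax(origin + mag * dirs[r, ], lo), hi)
            pb <- pmin(pmax(origin - mag * dirs[r, ], lo), hi)
            score <- sqrt(sum((pa - pb)^2))
            if (!is.null(others))
              score <- min(score, min(sqrt(rowSums(sweep(others, 2, pa)^2))),
                           min(sqrt(rowSums(sweep(others, 2, pb)^2))))
            if (score > best_score) { best_score <- score; best <- list(pa, pb) }
          }
          cells[[sib[1]]]$path[f, ] <- best[[1]]
          cells[[sib[2]]]$path[f, ] <- best[[2]]
        }
        next
      }
      prev <- cl$path[f - 1L, ]
      step <- stats::rnorm(3); step[3] <- step[3] * 0.3
      step <- step / sqrt(sum(step^2)) * stats::runif(1, 0, max_step_um)
      others <- NULL
      for (m in seq_along(cells)) {
        if (m == k) next
        om <- cells[[m]]
        if (f < om$birth || f > om$end) next
        op <- if (!any(is.na(om$path[f, ]))) om$path[f, ] else om$path[f - 1L, ]
        if (!any(is.na(op))) others <- rbind(others, op)
      }
      cand <- rbind(pmin(pmax(prev + step, lo), hi),
                    pmin(pmax(prev - step, lo), hi))
      if (!is.null(others)) {
        nearest <- apply(cand, 1, function(p)
          min(sqrt(rowSums(sweep(others, 2, p)^2))))
        pick <- if (min(nearest) < min_separation_um) which.max(nearest) else 1L
      } else pick <- 1L
      cells[[k]]$path[f, ] <- cand[pick, ]
    }
  }
  vessels <- list(
    list(p0 = c(0, extent[2] * 0.25, extent[3] * 0.2),
         p1 = c(extent[1], extent[2] * 0.35, extent[3] * 0.2), radius = 2.5),
    list(p0 = c(extent[1] * 0.7, 0, extent[3] * 0.3),
         p1 = c(extent[1] * 0.6, extent[2], extent[3] * 0.3), radius = 2))
  structure(list(cells = cells, vessels = vessels,
                 n_frames = as.integer(n_frames),
                 shape = as.integer(shape), seed = seed),
            class = "clone_plan")
}

# voxel rows (z,y,x) of an ellipsoid at center (x,y,z um) with radii (x,y,z um)
.ellipsoid_voxels <- function(center, radii, shape, spacing) {
  s <- c(spacing$dx, spacing$dy, spacing$dz)
  lo <- pmax(floor((center - radii) / s) + 1, 1)
  hi <- pmin(ceiling((center + radii) / s) + 1, shape[c(3, 2, 1)])
  if (any(hi < lo)) return(matrix(integer(0), 0, 3))
  g <- expand.grid(z = lo[3]:hi[3], y = lo[2]:hi[2], x = lo[1]:hi[1])
  px <- (g$x - 1) * s[1]; py <- (g$y - 1) * s[2]; pz <- (g$z - 1) * s[3]
  r2 <- ((px - center[1]) / radii[1])^2 + ((py - center[2]) / radii[2])^2 +
    ((pz - center[3]) / radii[3])^2
  as.matrix(g[r2 <= 1, c("z", "y", "x"), drop = FALSE])
}

.point_segment_dist <- function(pts, p0, p1) {
  v <- p1 - p0
  len2 <- sum(v^2)
  rel <- sweep(pts, 2, p0)
  t_ <- pmin(pmax(as.numeric(rel %*% v) / len2, 0), 1)
  sqrt(rowSums((rel - outer(t_, v))^2))
}

#' Rasterize and simulate a clone movie
#'
#' Renders the plan's ellipsoidal cells into the cell channel (solid
#' interior with a one-voxel Gaussian edge falloff so thresholding sees a
#' realistic boundary) and its static tube segments into the vessel channel,
#' adds noise, and emits ground truth in the same structures the pipeline
#' produces: per-frame detections (with frame-local ids), tracks, and the
#' lineage parent map. Deterministic for a fixed seed.
#'
#' @param plan A [random_clone_plan()] (or hand-built `clone_plan`).
#' @param spacing A [voxel_spacing()].
#' @param noise A [noise_model()].
#' @param seed Seed for the noise draws.
#' @param render If `FALSE`, skip rasterizing the intensity volume and
#'   return only ground truth (the truth is fully defined by the plan).
#' @return List: `volume` ([volume5d()] or `NULL`), `truth` with
#'   `detections` (per frame), `tracks`, `parents`, `division_frame`,
#'   `cell_of` (per frame, ground-truth cell id of each detection), `plan`.
#' @export
simulate_clone_movie <- function(plan, spacing, noise = noise_model(),
                                 seed = 0, render = TRUE) {
  shape <- plan$shape
  n_frames <- plan$n_frames
  dets_by_frame <- vector("list", n_frames)
  cell_of <- vector("list", n_frames)
  overlapping <- FALSE
  for (f in seq_len(n_frames)) {
    dets <- list(); owners <- integer(0); occupied <- integer(0)
    for (cl in plan$cells) {
      if (f < cl$birth || f > cl$end) next
      vox <- .ellipsoid_voxels(cl$path[f, ], cl$radii, shape, spacing)
      if (nrow(vox) == 0)
        stop("cell ", cl$id, " rasterized to zero voxels at frame ", f)
      lin <- vox[, 1] + shape[1] * ((vox[, 2] - 1) + shape[2] * (vox[, 3] - 1))
      if (any(lin %in% occupied)) overlapping <- TRUE
      occupied <- c(occupied, lin)
      dets[[length(dets) + 1L]] <- detection(f, vox, spacing,
                                             id = length(dets) + 1L)
      owners <- c(owners, cl$id)
    }
    dets_by_frame[[f]] <- dets
    cell_of[[f]] <- owners
  }
  if (overlapping)
    message("note: some ground-truth cells overlap (merge/split testing case)")
  tracks <- list()
  parents <- integer(0)
  division_frame <- integer(0)
  for (cl in plan$cells) {
    dd <- list()
    for (f in cl$birth:cl$end)
      dd[[as.character(f)]] <- dets_by_frame[[f]][[which(cell_of[[f]] == cl$id)]]
    tracks[[cl$id]] <- new_track(cl$id, dd)
    if (!is.na(cl$parent)) {
      parents[as.character(cl$id)] <- cl$parent
      division_frame[as.character(cl$parent)] <- plan$cells[[cl$parent]]$end
    }
  }
  volume <- NULL
  if (render) {
    set.seed(seed)
    data <- array(0, dim = c(n_frames, 2, shape))
    coords <- list(z = (seq_len(shape[1]) - 1) * spacing$dz,
                   y = (seq_len(shape[2]) - 1) * spacing$dy,
                   x = (seq_len(shape[3]) - 1) * spacing$dx)
    bgfield <- function() {
      ph <- stats::runif(3, 0, 2 * pi)
      fz <- cos(pi * coords$z / noise$background_scale + ph[1])
      fy <- cos(pi * coords$y / noise$background_scale + ph[2])
      fx <- cos(pi * coords$x / noise$background_scale + ph[3])
      noise$background_amp / 2 * (1 + outer(outer(fz, fy), fx))
    }
    bg <- list(bgfield(), bgfield())
    falloff_um <- min(spacing$dx, spacing$dy)
    # vessels are static: rasterize once
    g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                     x = seq_len(shape[3]))
    pts <- cbind((g$x - 1) * spacing$dx, (g$y - 1) * spacing$dy,
                 (g$z - 1) * spacing$dz)
    vesv <- array(0, dim = shape)
    for (vs in plan$vessels) {
      d <- .point_segment_dist(pts, vs$p0, vs$p1)
      val <- 100 * exp(-pmax(d - vs$radius, 0)^2 / (2 * falloff_um^2))
      vesv <- pmax(vesv, array(val, dim = shape))
    }
    for (f in seq_len(n_frames)) {
      cellv <- array(0, dim = shape)
      for (cl in plan$cells) {
        if (f < cl$birth || f > cl$end) next
        center <- cl$path[f, ]; radii <- cl$radii
        s <- c(spacing$dx, spacing$dy, spacing$dz)
        pad <- 3 * falloff_um
        blo <- pmax(floor((center - radii - pad) / s) + 1, 1)
        bhi <- pmin(ceiling((center + radii + pad) / s) + 1, shape[c(3, 2, 1)])
        bg2 <- expand.grid(z = blo[3]:bhi[3], y = blo[2]:bhi[2], x = blo[1]:bhi[1])
        px <- (bg2$x - 1) * s[1]; py <- (bg2$y - 1) * s[2]; pz <- (bg2$z - 1) * s[3]
        rho <- sqrt(((px - center[1]) / radii[1])^2 +
                    ((py - center[2]) / radii[2])^2 +
                    ((pz - center[3]) / radii[3])^2)
        excess <- pmax(rho - 1, 0) * mean(radii)
        val <- cl$intensity * exp(-excess^2 / (2 * falloff_um^2))
        idx <- cbind(bg2$z, bg2$y, bg2$x)
        cellv[idx] <- pmax(cellv[idx], val)
      }
      for (ch in 1:2) {
        base <- if (ch == 1) cellv else vesv
        img <- base + bg[[ch]] + stats::rnorm(length(base), 0, noise$gaussian_sd)
        salt <- stats::runif(length(base)) < noise$salt_prob
        img[salt] <- img[salt] + noise$salt_amp
        data[f, ch, , , ] <- pmax(round(img), 0)
      }
    }
    volume <- volume5d(data, spacing, channel_roles = c("cell", "vessel"))
  }
  list(volume = volume,
       truth = list(detections = dets_by_frame, tracks = tracks,
                    parents = parents, division_frame = division_frame,
                    cell_of = cell_of),
       plan = plan)
}

#' Frame-to-frame mask overlap of one cell
#'
#' `|A intersect B| / min(|A|, |B|)` between two voxel masks on the same
#' grid - the quantity whose 50% bound underwrites error-free tracking.
#'
#' @param det_t,det_t1 [detection()]s (consecutive ground-truth masks of one
#'   cell).
#' @param shape (z, y, x) grid dimensions.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(det_t, det_t1, shape) {
  if (det_t$voxel_count == 0 || det_t1$voxel_count == 0) stop("empty mask")
  lin <- function(v) v[, 1] + shape[1] * ((v[, 2] - 1) + shape[2] * (v[, 3] - 1))
  length(intersect(lin(det_t$voxels), lin(det_t1$voxels))) /
    min(det_t$voxel_count, det_t1$voxel_count)
}

#' Minimum frame-to-frame overlap across a simulated truth
#'
#' Smallest [overlap_fraction()] over all cells and consecutive frame pairs
#' of a simulated movie's ground truth.
#'
#' @param truth The `truth` element of [simulate_clone_movie()].
#' @param shape (z, y, x) grid dimensions.
#' @return Scalar fraction.
#' @export
min_overlap_fraction <- function(truth, shape) {
  worst <- 1
  for (tr in truth$tracks) {
    frames <- as.integer(names(tr$detections))
    if (length(frames) < 2) next
    for (k in seq_len(length(frames) - 1)) {
      if (frames[k + 1] != frames[k] + 1) next
      worst <- min(worst, overlap_fraction(tr$detections[[k]],
                                           tr$detections[[k + 1]], shape))
    }
  }
  worst
}

#' Simulate an overlapping tile montage from a master volume
#'
#' Cuts a `rows x cols` grid of overlapping tiles out of one master 3-D
#' array (so the master is ground truth for fusion), records the true voxel
#' offsets, and jitters the stage metadata by a bounded uniform integer
#' perturbation to emulate specimen shift relative to the stage.
#'
#' @param master 3-D array (z, y, x), single channel.
#' @param grid `c(rows, cols)` tile layout (rows along y, cols along x).
#' @param overlap Fractional overlap between neighbouring tiles (>= 0.1).
#' @param jitter Maximum absolute stage error, voxels per axis (x and y;
#'   the single z subsection is not jittered in z).
#' @param seed Integer seed for the jitter draws.
#' @param spacing A [voxel_spacing()].
#' @return List: `tiles` (list of [tile()] with jittered stage positions),
#'   `true_positions_vox` (matrix of true (x, y, z) voxel origins).
#' @export
simulate_montage <- function(master, grid, overlap = 0.15, jitter = 0,
                             seed = 0, spacing = voxel_spacing(1, 1, 1)) {
  if (overlap < 0.1) stop("overlap must be >= 10%")
  set.seed(seed)
  d <- dim(master)  # (z, y, x)
  rows <- grid[1]; cols <- grid[2]
  tw <- function(n, k) floor(n / (k - (k - 1) * overlap))
  wx <- tw(d[3], cols); wy <- tw(d[2], rows)
  if (wx < 2 || wy < 2) stop("grid larger than master")
  x0 <- round(seq(0, d[3] - wx, length.out = cols))
  y0 <- round(seq(0, d[2] - wy, length.out = rows))
  tiles <- list(); truth <- NULL
  id <- 1L
  for (r in seq_len(rows)) for (c2 in seq_len(cols)) {
    vol <- master[, (y0[r] + 1):(y0[r] + wy), (x0[c2] + 1):(x0[c2] + wx),
                  drop = FALSE]
    true_pos <- c(x0[c2], y0[r], 0)
    jit <- if (jitter > 0) c(sample(-jitter:jitter, 2, replace = TRUE), 0)
           else c(0, 0, 0)
    stage_um <- (true_pos + jit) * c(spacing$dx, spacing$dy, spacing$dz)
    tiles[[id]] <- tile(id, list(vol), stage_um, spacing)
    truth <- rbind(truth, true_pos)
    id <- id + 1L
  }
  list(tiles = tiles, true_positions_vox = truth)
}

#' Synthetic vessel-like master volume for montage tests
#'
#' A reproducible 3-D array with bright tube structures over a textured
#' background, with enough unique detail everywhere that any overlapping
#' sub-region registers unambiguously.
#'
#' @param shape (z, y, x) voxel counts.
#' @param seed Integer seed.
#' @param n_tubes Number of random tube segments; by default scales with the
#'   lateral field area so that vessel structure spans every subregion, the
#'   premise of covariance-based tile registration.
#' @param amplitude Peak tube intensity.
#' @return 3-D numeric array.
#' @export
simulate_vessel_master <- function(shape, seed = 0,
                                   n_tubes = max(12, round(shape[2] * shape[3] / 2200)),
                                   amplitude = 90) {
  set.seed(seed)
  g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                   x = seq_len(shape[3]))
  pts <- cbind(g$x, g$y, g$z)
  out <- array(0, dim = shape)
  ext <- c(shape[3], shape[2], shape[1])
  for (k in seq_len(n_tubes)) {
    # curved tube: quadratic Bezier sampled as a short polyline; vessels bend
    # and branch, which also keeps tile registration well-posed (a straight
    # tube parallel to an overlap strip pins no offset along its own axis)
    p0 <- stats::runif(3, 0, ext); p1 <- stats::runif(3, 0, ext)
    pc <- (p0 + p1) / 2 + stats::runif(3, -0.35, 0.35) * ext
    bez <- function(t) (1 - t)^2 %o% p0 + (2 * t * (1 - t)) %o% pc + t^2 %o% p1
    knots <- bez(seq(0, 1, length.out = 6))
    r <- stats::runif(1, 1.5, 3)
    d <- rep(Inf, nrow(pts))
    for (s in seq_len(nrow(knots) - 1))
      d <- pmin(d, .point_segment_dist(pts, knots[s, ], knots[s + 1, ]))
    out <- pmax(out, array(amplitude * exp(-pmax(d - r, 0)^2 / 2), dim = shape))
  }
  texture <- array(stats::runif(prod(shape), 0, amplitude / 4), dim = shape)
  texture <- cpp_median3(as.numeric(texture), as.integer(shape))
  round(out + array(texture, dim = shape))
}
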