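# Shared fixtures and independent oracles, all built in code.

iso_spacing <- function() voxel_spacing(1, 1, 1)

# ellipsoid voxel mask helper (goes through the simulator's rasterizer)
ellipsoid_vox <- function(center_xyz, radii_xyz, shape, spacing) {
  clonetrack:::.ellipsoid_voxels(center_xyz, radii_xyz, shape, spacing)
}

# canonical signature of a track: its (frame, detection-id) chain
track_sig <- function(tr) {
  paste(names(tr$detections),
        vapply(tr$detections, function(d) d$id, integer(1)),
        sep = ":", collapse = ";")
}

# compare a recovered forest against simulator truth: detection partition
# equality and parent-edge equality (up to track relabelling)
forest_matches_truth <- function(forest, truth) {
  got <- sort(vapply(forest$tracks, track_sig, ""))
  want <- sort(vapply(truth$tracks, track_sig, ""))
  if (!identical(got, want)) return(FALSE)
  gmap <- stats::setNames(vapply(forest$tracks, track_sig, ""),
                          vapply(forest$tracks, function(t) t$id, integer(1)))
  wmap <- stats::setNames(vapply(truth$tracks, track_sig, ""),
                          vapply(truth$tracks, function(t) t$id, integer(1)))
  gedges <- character(0)
  for (id in names(forest$parent)) {
    p <- forest$parent[[id]]
    if (!is.na(p)) gedges <- c(gedges, paste(gmap[[id]], gmap[[as.character(p)]]))
  }
  wedges <- vapply(names(truth$parents), function(id)
    paste(wmap[[id]], wmap[[as.character(truth$parents[[id]])]]), "")
  identical(sort(gedges), sort(unname(wedges)))
}

# brute-force Otsu: maximize between-class variance by looping candidate bins
oracle_otsu_threshold <- function(v, nbins = 256) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = nbins + 1)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins)
  counts <- tabulate(bin, nbins)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  best <- -Inf; best_k <- 1
  for (k in 1:(nbins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):nbins] * mids[(k + 1):nbins]) / w1
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  edges[best_k + 1]
}

# O(N^2) anisotropic distance map
oracle_distance_map <- function(mask, spacing) {
  d <- dim(mask)
  out <- array(Inf, dim = d)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(out)
  fg_um <- cbind(fg[, 3] * spacing$dx, fg[, 2] * spacing$dy, fg[, 1] * spacing$dz)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    p <- c(x * spacing$dx, y * spacing$dy, z * spacing$dz)
    out[z, y, x] <- sqrt(min(rowSums(sweep(fg_um, 2, p)^2)))
  }
  out
}

# all-pairs scan for the minimum inter-detection distance
oracle_cc_distance <- function(a, b, spacing) {
  pa <- voxel_coords_um(a$voxels, spacing)
  pb <- voxel_coords_um(b$voxels, spacing)
  best <- Inf
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
    best <- min(best, sqrt(sum((pa[i, ] - pb[j, ])^2)))
  best
}

# enumerate all spanning trees of a small edge list, return max total weight
oracle_max_spanning_weight <- function(edges_df, nodes) {
  n <- length(nodes); m <- nrow(edges_df)
  best <- -Inf
  for (sel in utils::combn(m, n - 1, simplify = FALSE)) {
    sub <- edges_df[sel, ]
    parent <- stats::setNames(nodes, nodes)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    ok <- TRUE
    for (k in seq_len(nrow(sub))) {
      ra <- find(as.character(sub$a[k])); rb <- find(as.character(sub$b[k]))
      if (ra == rb) { ok <- FALSE; break }
      parent[[ra]] <- rb
    }
    if (ok) best <- max(best, sum(sub$score))
  }
  best
}

# construct a movie state whose two post-mitotic daughters stay merged for
# `merged_frames` frames after the division (segmentation-style merge)
make_merge_scenario <- function(merged_frames = 3, spacing = iso_spacing()) {
  shape <- c(20, 48, 48)
  radii <- c(3.2, 3, 2.5)
  pcenter <- c(24, 24, 10)
  sep_start <- merged_frames + 3L
  dA <- function(f) pcenter + c(-3.2 - 0.9 * max(0, f - sep_start + 1), 0, 0)
  dB <- function(f) pcenter + c(3.2 + 0.9 * max(0, f - sep_start + 1), 0, 0)
  n_frames <- 2L + merged_frames + 3L
  dets <- vector("list", n_frames)
  for (f in 1:2)
    dets[[f]] <- list(detection(f, ellipsoid_vox(pcenter, radii, shape, spacing),
                                spacing, id = 1L))
  for (f in 3:(2 + merged_frames))
    dets[[f]] <- list(detection(
      f, unique(rbind(ellipsoid_vox(dA(f), radii, shape, spacing),
                      ellipsoid_vox(dB(f), radii, shape, spacing))),
      spacing, id = 1L))
  for (f in (3 + merged_frames):n_frames)
    dets[[f]] <- list(
      detection(f, ellipsoid_vox(dA(f), radii, shape, spacing), spacing, id = 1L),
      detection(f, ellipsoid_vox(dB(f), radii, shape, spacing), spacing, id = 2L))
  list(dets = dets, shape = shape, division_frame = 2L,
       merged = 3:(2 + merged_frames), n_frames = n_frames)
}

# small deterministic two-channel movie for pipeline tests
small_sim <- function(seed = 1, n_frames = 6, n_founders = 2, n_divisions = 0,
                      render = TRUE) {
  sp <- voxel_spacing(0.8, 0.8, 1)
  plan <- random_clone_plan(n_frames, c(15, 48, 48), sp, seed = seed,
                            n_founders = n_founders, n_divisions = n_divisions)
  list(sim = simulate_clone_movie(plan, sp, seed = seed, render = render),
       spacing = sp, plan = plan)
}
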