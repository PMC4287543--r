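sp1 <- voxel_spacing(1, 1, 1)

test_that("Otsu separates a bimodal image and matches brute-force search", {
  v <- array(c(rep(0, 32), rep(255, 32)), dim = c(4, 4, 4))
  mask <- otsu_threshold(v)
  expect_identical(unname(which(mask)), unname(which(v == 255)))
  set.seed(1)
  for (rep in 1:5) {
    v <- array(c(rnorm(200, 20, 6), rnorm(160, 90, 12)), dim = c(6, 6, 10))
    mask <- otsu_threshold(v)
    expect_equal(attr(mask, "threshold"), oracle_otsu_threshold(v))
  }
  expect_warning(m0 <- otsu_threshold(array(5, dim = c(3, 3, 3))), "constant")
  expect_false(any(m0))
})

test_that("closing fills interior holes and never removes foreground", {
  cube <- array(FALSE, dim = c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  expect_identical(close_binary(cube, 1, sp1), cube)
  holed <- cube; holed[5, 5, 5] <- FALSE
  expect_identical(close_binary(holed, 1, sp1), cube)
  set.seed(2)
  blob <- array(runif(7^3) > 0.6, dim = c(7, 7, 7))
  closed <- close_binary(blob, 1.5, sp1)
  expect_true(all(closed[blob]))  # output contains input
  # equals explicit dilation-then-erosion with the same ball
  offs <- clonetrack:::.ball_offsets(1.5, sp1)
  dil <- array(FALSE, dim = dim(blob))
  for (k in seq_len(nrow(offs)))
    dil <- dil | clonetrack:::.shift_mask(blob, offs[k, ], FALSE)
  ero <- array(TRUE, dim = dim(blob))
  for (k in seq_len(nrow(offs)))
    ero <- ero & clonetrack:::.shift_mask(dil, -offs[k, ], TRUE)
  expect_identical(closed, ero)
})

test_that("volume filter keeps components at or above 19 um^3 and discards below", {
  v <- array(FALSE, dim = c(10, 30, 30))
  v[2, 2, 2:11] <- TRUE                 # 10 voxels = 10 um^3 -> discarded
  v[5, 10:14, 10:13] <- TRUE            # 20 voxels... make exactly 19
  v[5, 10, 10] <- FALSE                 # 19 voxels = 19 um^3 -> kept
  v[8, 20:24, 20:25] <- TRUE            # 30 voxels -> kept
  dets <- extract_detections(v, sp1, segmentation_params(min_volume_um3 = 19))
  expect_length(dets, 2)
  expect_setequal(vapply(dets, function(d) d$voxel_count, integer(1)), c(19L, 30L))
  # anisotropic voxels: 200 voxels at 0.5^3 um = 25 um^3 -> kept
  sph <- voxel_spacing(0.5, 0.5, 0.5)
  v2 <- array(FALSE, dim = c(10, 10, 10)); v2[1:5, 1:5, 1:8] <- TRUE
  d2 <- extract_detections(v2, sph, segmentation_params(min_volume_um3 = 19))
  expect_length(d2, 1)
  expect_equal(d2[[1]]$volume_um3, 200 * 0.125)
})

test_that("components are 26-connected and deterministically ordered", {
  v <- array(FALSE, dim = c(4, 6, 6))
  v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE  # diagonal touch: one component
  dets <- extract_detections(v, sp1, segmentation_params(min_volume_um3 = 0.5))
  expect_length(dets, 1)
  v[4, 6, 6] <- TRUE
  dets <- extract_detections(v, sp1, segmentation_params(min_volume_um3 = 0.5))
  expect_length(dets, 2)
  again <- extract_detections(v, sp1, segmentation_params(min_volume_um3 = 0.5))
  expect_identical(lapply(dets, function(d) d$voxels),
                   lapply(again, function(d) d$voxels))
})

test_that("convex hull: cube, tetrahedron, containment, degenerate fallback", {
  cube <- convex_hull(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(hull_volume(cube), 1)
  expect_identical(nrow(cube$vertices), 8L)
  expect_false(cube$degenerate)
  tet <- convex_hull(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_identical(nrow(tet$faces), 4L)
  set.seed(3)
  pts <- matrix(rnorm(150), ncol = 3)
  h <- convex_hull(pts)
  expect_true(all(hull_contains(h, pts, tol = 1e-7)))  # half-space oracle
  flat <- convex_hull(cbind(runif(10), runif(10), 0))
  expect_true(flat$degenerate)
  # detection-based hull contains every voxel center, volume is sane
  det <- detection(1, ellipsoid_vox(c(8, 8, 5), c(4, 3, 2.5), c(12, 16, 16), sp1),
                   sp1)
  hd <- convex_hull(det, sp1)
  expect_true(all(hull_contains(hd, voxel_coords_um(det$voxels, sp1), 1e-6)))
  expect_gte(hull_volume(hd), 0.5 * det$volume_um3)
})

test_that("distance map matches the brute-force oracle on anisotropic grids", {
  # single x-neighbour at dx = 0.8
  sp <- voxel_spacing(0.8, 1, 1)
  m <- array(FALSE, dim = c(1, 1, 3)); m[1, 1, 2] <- TRUE
  dm <- vessel_distance_map(m, sp)
  expect_equal(dm[1, 1, 1], 0.8)
  expect_equal(dm[1, 1, 2], 0)
  spa <- voxel_spacing(1, 1, 2)
  set.seed(4)
  for (rep in 1:3) {
    m <- array(runif(125) > 0.8, dim = c(5, 5, 5))
    if (!any(m)) m[3, 3, 3] <- TRUE
    expect_equal(vessel_distance_map(m, spa), oracle_distance_map(m, spa),
                 tolerance = 1e-10)
  }
  expect_warning(inf_map <- vessel_distance_map(array(FALSE, dim = c(3, 3, 3)), spa),
                 "empty")
  expect_true(all(is.infinite(inf_map)))
})

test_that("distance map equals brute force on every mask of a small exhaustive family", {
  spa <- voxel_spacing(0.8, 1.1, 2)
  set.seed(5)
  for (rep in 1:8) {
    d <- sample(2:8, 3, replace = TRUE)
    m <- array(runif(prod(d)) > runif(1, 0.3, 0.9), dim = d)
    if (!any(m)) next
    expect_equal(vessel_distance_map(m, spa), oracle_distance_map(m, spa),
                 tolerance = 1e-10)
  }
})

test_that("segment_movie recovers well-separated ellipsoids with accurate centroids", {
  s <- small_sim(seed = 6, n_frames = 3, n_founders = 3)
  seg <- segment_movie(s$sim$volume)
  for (f in 1:3) {
    expect_length(seg$detections[[f]], 3)
    gt <- t(vapply(s$sim$truth$detections[[f]], function(d) d$centroid_um,
                   numeric(3)))
    got <- t(vapply(seg$detections[[f]], function(d) d$centroid_um, numeric(3)))
    for (k in 1:3) {
      errs <- sqrt(rowSums(sweep(gt, 2, got[k, ])^2))
      expect_lt(min(errs), 1)  # within one voxel of a true centroid
    }
    expect_false(is.null(seg$detections[[f]][[1]]$hull))
  }
  expect_true(all(seg$distance_maps[[1]] >= 0))
})

test_that("sub-threshold speckles never become detections", {
  s <- small_sim(seed = 7, n_frames = 2, n_founders = 2)
  vol <- s$sim$volume
  # plant bright single-voxel speckles into the cell channel
  set.seed(7)
  for (f in 1:2) {
    fr <- get_frame(vol, f, "cell")
    idx <- cbind(sample(3:13, 6), sample(3:45, 6), sample(3:45, 6))
    fr[idx] <- 400
    vol$data[f, 1, , , ] <- fr
  }
  seg <- segment_movie(vol)
  expect_true(all(vapply(seg$detections, length, integer(1)) == 2))
  expect_true(all(unlist(lapply(seg$detections, function(fr)
    vapply(fr, function(d) d$volume_um3, numeric(1)))) >= 19))
})
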