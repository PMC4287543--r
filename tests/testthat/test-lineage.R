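sp1 <- voxel_spacing(1, 1, 1)

test_that("parent assignment picks the argmin-cost candidate or none", {
  # two candidate parents at frame 1; newborn at frame 2 nearer candidate 1
  dets <- list(
    list(detection(1, cbind(2, 2, 2), sp1, id = 1L),
         detection(1, cbind(2, 2, 12), sp1, id = 2L)),
    list(detection(2, cbind(2, 2, 2), sp1, id = 1L),
         detection(2, cbind(2, 2, 12), sp1, id = 2L),
         detection(2, cbind(2, 2, 5), sp1, id = 3L)))
  tr <- track_movie(dets, sp1)
  newborn <- Filter(function(t) t$birth == 2L, tr$tracks)[[1]]
  expect_identical(assign_parent(newborn, tr), 1L)
  # newborn farther than max_link_distance from everything: stays a root
  dets2 <- list(list(detection(1, cbind(2, 2, 2), sp1, id = 1L)),
                list(detection(2, cbind(2, 2, 2), sp1, id = 1L),
                     detection(2, cbind(9, 45, 45), sp1, id = 2L)))
  tr2 <- track_movie(dets2, sp1, cost_params(max_link_distance = 10))
  nb2 <- Filter(function(t) t$birth == 2L, tr2$tracks)[[1]]
  expect_true(is.na(assign_parent(nb2, tr2)))
})

test_that("forest building splits the parent at the division", {
  s <- make_merge_scenario(merged_frames = 0)
  tr <- track_movie(s$dets, iso_spacing())
  lin <- lineage_movie(tr)
  f <- lin$forest
  expect_length(f$tracks, 3)
  expect_length(f$trees, 1)
  kids <- names(f$parent)[!is.na(f$parent)]
  expect_length(kids, 2)
  parent_id <- unique(unlist(f$parent[kids]))
  expect_length(parent_id, 1)
  by_id <- stats::setNames(f$tracks, vapply(f$tracks, function(t) t$id, integer(1)))
  expect_identical(by_id[[as.character(parent_id)]]$end,
                   unname(f$division_frame[as.character(parent_id)]))
  for (k in kids)
    expect_identical(by_id[[k]]$birth,
                     unname(f$division_frame[as.character(parent_id)]) + 1L)
})

test_that("a cyclic parent assignment errors; singletons form singleton trees", {
  d <- function(f, id) detection(f, cbind(1, 1, 1), sp1, id = id)
  t1 <- new_track(1L, list(`1` = d(1, 1L), `2` = d(2, 1L)))
  t2 <- new_track(2L, list(`1` = d(1, 2L), `2` = d(2, 2L)))
  expect_error(build_forest(list(t1, t2), c(`1` = 2L, `2` = 1L)), "cycle")
  f <- build_forest(list(t1, t2), integer(0))
  expect_length(f$trees, 2)
  expect_true(all(is.na(f$parent)))
})

test_that("largest tree selection prefers size, then earliest root, then id", {
  s <- small_sim(seed = 11, n_frames = 10, n_founders = 3, n_divisions = 1,
                 render = FALSE)
  lin <- lineage_movie(track_movie(s$sim$truth$detections, s$spacing))
  root <- largest_tree(lin$forest)
  expect_identical(length(lin$forest$trees[[as.character(root)]]),
                   max(vapply(lin$forest$trees, length, integer(1))))
  # all singletons: lowest root id wins
  d <- function(f, id) detection(f, cbind(1, 1, id * 3), sp1, id = id)
  ts <- lapply(1:3, function(k) new_track(k, stats::setNames(list(d(1, k)), "1")))
  f2 <- build_forest(ts, integer(0))
  expect_identical(largest_tree(f2), 1L)
  expect_error(largest_tree(build_forest(list(), integer(0))), "empty|non-empty")
})

test_that("niche series equals a brute-force cell-to-vessel minimum", {
  sp <- voxel_spacing(1, 1, 2)
  vessel <- array(FALSE, dim = c(6, 8, 8)); vessel[2, 2, 2] <- TRUE
  dm <- vessel_distance_map(vessel, sp)
  det1 <- detection(1, rbind(c(5, 6, 3), c(5, 6, 4)), sp, id = 1L)
  trk <- new_track(1L, list(`1` = det1))
  got <- niche_series(trk, list(dm))
  # O(N^2) oracle over voxel pairs
  vd <- voxel_coords_um(which(vessel, arr.ind = TRUE)[, c(1, 2, 3), drop = FALSE], sp)
  cd <- voxel_coords_um(det1$voxels, sp)
  want <- min(apply(cd, 1, function(p) sqrt(min(rowSums(sweep(vd, 2, p)^2)))))
  expect_equal(got$distance_um, want)
  # touching the vessel gives zero; a 5-voxel x gap gives 5 um
  sp0 <- voxel_spacing(1, 1, 1)
  vessel2 <- array(FALSE, dim = c(3, 3, 12)); vessel2[2, 2, 1:2] <- TRUE
  dm2 <- vessel_distance_map(vessel2, sp0)
  touching <- new_track(1L, list(`1` = detection(1, cbind(2, 2, 2), sp0, id = 1L)))
  expect_identical(niche_series(touching, list(dm2))$distance_um, 0)
  away <- new_track(2L, list(`1` = detection(1, cbind(2, 2, 7), sp0, id = 1L)))
  expect_equal(niche_series(away, list(dm2))$distance_um, 5)
  expect_error(niche_series(away, list()), "no distance map")
})

test_that("cleavage plane is the perpendicular bisector of the daughters", {
  da <- detection(3, cbind(1, 1, 1), sp1)   # centroid (0, 0, 0)
  db <- detection(3, cbind(1, 1, 3), sp1)   # centroid (2, 0, 0)
  cp <- cleavage_plane(da, db)
  expect_equal(cp$point, c(x = 1, y = 0, z = 0))
  expect_equal(unname(cp$normal), c(1, 0, 0))
  dc <- detection(3, cbind(5, 1, 1), sp1)   # centroid (0, 0, 4)
  cp2 <- cleavage_plane(da, dc)
  expect_equal(unname(cp2$point), c(0, 0, 2))
  expect_equal(unname(cp2$normal), c(0, 0, 1))
  expect_error(cleavage_plane(da, da), "coincident")
  expect_error(cleavage_plane(da, detection(4, cbind(1, 1, 3), sp1)), "birth frame")
  # random pair: midpoint and unit normal match direct arithmetic
  set.seed(5)
  va <- cbind(sample(1:9, 5, TRUE), sample(1:9, 5, TRUE), sample(1:9, 5, TRUE))
  vb <- cbind(sample(1:9, 5, TRUE), sample(1:9, 5, TRUE), sample(1:9, 5, TRUE))
  d1 <- detection(1, va, sp1); d2 <- detection(1, vb, sp1)
  cp3 <- cleavage_plane(d1, d2)
  expect_equal(unname(cp3$point), unname((d1$centroid_um + d2$centroid_um) / 2))
  dvec <- d2$centroid_um - d1$centroid_um
  expect_equal(unname(cp3$normal), unname(dvec / sqrt(sum(dvec^2))))
  expect_equal(sqrt(sum(cp3$normal^2)), 1)
})

test_that("recovered trees are isomorphic to the simulated truth across seeds", {
  for (seed in 21:25) {
    s <- small_sim(seed = seed, n_frames = 12, n_founders = 2, n_divisions = 2,
                   render = FALSE)
    lin <- lineage_movie(track_movie(s$sim$truth$detections, s$spacing))
    expect_true(forest_matches_truth(lin$forest, s$sim$truth),
                label = paste("seed", seed))
    # forest partition: every track in exactly one tree
    all_ids <- unname(unlist(lin$forest$trees))
    expect_identical(sort(all_ids),
                     sort(vapply(lin$forest$tracks, function(t) t$id, integer(1))))
  }
})
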