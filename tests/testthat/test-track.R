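sp1 <- voxel_spacing(1, 1, 1)

det_at <- function(zyx, frame = 1L, id = 1L, extra = NULL) {
  detection(frame, rbind(zyx, extra), sp1, id = id)
}

test_that("connected-component distance respects overlap, geometry and anisotropy", {
  a <- detection(1, rbind(c(1, 1, 1), c(1, 1, 2)), sp1)
  b <- detection(2, rbind(c(1, 1, 2), c(1, 1, 3)), sp1)
  expect_identical(cc_distance(a, b, sp1), 0)
  a <- det_at(c(1, 1, 1)); b <- det_at(c(1, 5, 4), 2)
  expect_equal(cc_distance(a, b, sp1), 5)  # 3-4-5 triangle
  spz <- voxel_spacing(1, 1, 2)
  a <- det_at(c(1, 1, 1)); b <- det_at(c(4, 1, 1), 2)
  expect_equal(cc_distance(a, b, spz), 6)  # 3 z-steps at dz = 2
  # random pairs vs the all-pairs scan oracle
  set.seed(1)
  spa <- voxel_spacing(0.8, 1, 2)
  for (rep in 1:5) {
    va <- cbind(sample(1:6, 8, TRUE), sample(1:6, 8, TRUE), sample(1:6, 8, TRUE))
    vb <- cbind(sample(4:9, 8, TRUE), sample(4:9, 8, TRUE), sample(4:9, 8, TRUE))
    da <- detection(1, va, spa); db <- detection(2, vb, spa)
    expect_equal(cc_distance(da, db, spa), oracle_cc_distance(da, db, spa))
  }
})

test_that("size distance is the normalized count difference", {
  mk <- function(n) detection(1, cbind(1, 1, seq_len(n)), sp1)
  expect_identical(size_distance(mk(5), mk(5)), 0)
  expect_equal(size_distance(mk(100), mk(50)), 0.5)
  expect_equal(size_distance(mk(1), mk(1000)), 0.999)
  expect_identical(size_distance(mk(3), mk(7)), size_distance(mk(7), mk(3)))
})

test_that("path cost follows the windowed weighted-sum form", {
  p <- cost_params(W = 4, lambda = 1)
  tau <- new_track(1L, list(`1` = det_at(c(1, 1, 1))))
  # static detection repeated: zero cost
  rho <- list(det_at(c(1, 1, 1), 2), det_at(c(1, 1, 1), 3))
  expect_identical(path_cost(tau, rho, p, sp1), 0)
  # single link of length 5, equal sizes: W/1 * 5 = 20
  expect_equal(path_cost(tau, list(det_at(c(1, 5, 4), 2)), p, sp1), 20)
  # lambda = 0 reduces to a pure distance sum scaled by W/|rho|
  p0 <- cost_params(W = 4, lambda = 0)
  big <- detection(2, cbind(1, 5, 4:8), sp1)  # different size
  expect_equal(path_cost(tau, list(big), p0, sp1), 4 * 5)
  # size term inflates the cost when lambda > 0
  expect_gt(path_cost(tau, list(big), p, sp1), 20)
  # links beyond max_link_distance are infeasible
  pshort <- cost_params(max_link_distance = 3)
  expect_identical(path_cost(tau, list(det_at(c(1, 5, 4), 2)), pshort, sp1), Inf)
  # the W/|rho| term makes a longer feasible path cheaper than a short one
  rho1 <- list(det_at(c(1, 1, 2), 2))
  rho2 <- list(det_at(c(1, 1, 2), 2), det_at(c(1, 1, 2), 3))
  expect_lt(path_cost(tau, rho2, p, sp1), path_cost(tau, rho1, p, sp1))
  expect_error(path_cost(tau, list(det_at(c(1, 1, 2), 2), det_at(c(1, 1, 3), 4)),
                         p, sp1), "consecutive")
})

test_that("best extension follows a smooth path and matches hand evaluation", {
  p <- cost_params(W = 4, lambda = 1)
  dets <- list(
    list(det_at(c(1, 1, 1), 1)),
    list(det_at(c(1, 1, 3), 2)),
    list(det_at(c(1, 1, 5), 3)),
    list(det_at(c(1, 1, 7), 4)))
  tau <- new_track(1L, list(`1` = dets[[1]][[1]]))
  ext <- best_extension(tau, dets, 1, p, sp1)
  expect_identical(ext$best_j, 1L)
  expect_equal(ext$best_cost, (4 / 3) * (2 + 2 + 2))  # hand-computed
  # every candidate beyond the feasibility gate: no extension
  far <- list(list(det_at(c(1, 1, 1), 1)), list(det_at(c(1, 40, 40), 2)))
  expect_null(best_extension(new_track(1L, list(`1` = far[[1]][[1]])),
                             far, 1, cost_params(max_link_distance = 10), sp1))
})

test_that("mutual-minimum matching resolves the documented cost matrices", {
  m <- match_frame(matrix(c(1, 4, 5, 2), 2, 2))  # [[1,5],[4,2]]
  expect_identical(m$matches, rbind(c(1L, 1L), c(2L, 2L)))
  m <- match_frame(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]]
  expect_identical(m$matches, rbind(c(1L, 1L)))
  expect_identical(m$new_detections, 2L)
  expect_identical(m$unextended, 2L)
  # empty detection set: every track unextended
  m <- match_frame(matrix(numeric(0), 2, 0))
  expect_null(m$matches)
  expect_identical(m$unextended, 1:2)
  # invariance under row/column permutation (up to relabeling)
  set.seed(2)
  costs <- matrix(runif(12), 3, 4)
  base <- match_frame(costs)$matches
  pr <- sample(3); pc <- sample(4)
  perm <- match_frame(costs[pr, pc])$matches
  remapped <- cbind(pr[perm[, 1]], pc[perm[, 2]])
  expect_identical(base[order(base[, 1]), , drop = FALSE],
                   remapped[order(remapped[, 1]), , drop = FALSE])
})

test_that("a static cell yields one full-length track", {
  dets <- lapply(1:10, function(f) list(det_at(c(2, 3, 4), f)))
  tr <- track_movie(dets, sp1)
  expect_length(tr$tracks, 1)
  expect_identical(length(tr$tracks[[1]]$detections), 10L)
})

test_that("two crossing cells with high self-overlap keep their identities", {
  shape <- c(10, 30, 60)
  radii <- c(2.8, 2.8, 2.2)
  # cells pass each other along x in different y lanes
  mk <- function(f, cx, cy) detection(f, ellipsoid_vox(c(cx, cy, 5), radii,
                                                       shape, sp1), sp1)
  dets <- lapply(1:12, function(f) {
    l <- list(mk(f, 8 + 2 * f, 12), mk(f, 40 - 2 * f, 18))
    for (k in seq_along(l)) l[[k]]$id <- k
    l
  })
  tr <- track_movie(dets, sp1)
  expect_length(tr$tracks, 2)
  for (t in tr$tracks) expect_identical(length(t$detections), 12L)
  # identities: track 1 follows the left-to-right cell (detection id 1 always)
  ids1 <- vapply(tr$tracks[[1]]$detections, function(d) d$id, integer(1))
  expect_true(all(ids1 == ids1[1]))
})

test_that("a one-frame occlusion is bridged into a single track", {
  dets <- lapply(1:7, function(f) {
    if (f == 4) list() else list(det_at(c(2, 3, 3 + f), f))
  })
  tr <- track_movie(dets, sp1, cost_params(occlusion_gap = 1))
  expect_length(tr$tracks, 1)
  expect_identical(as.integer(names(tr$tracks[[1]]$detections)),
                   c(1:3, 5:7))
  # with occlusion_gap = 0 the track is cut in two
  tr0 <- track_movie(dets, sp1, cost_params(occlusion_gap = 0))
  expect_length(tr0$tracks, 2)
})

test_that("tracking partitions the detections exactly", {
  s <- small_sim(seed = 3, n_frames = 8, n_founders = 3, n_divisions = 1,
                 render = FALSE)
  dets <- s$sim$truth$detections
  tr <- track_movie(dets, s$spacing)
  seen <- unlist(lapply(tr$tracks, function(t)
    paste(names(t$detections), vapply(t$detections, function(d) d$id, integer(1)))))
  expect_identical(length(seen), sum(vapply(dets, length, integer(1))))
  expect_false(any(duplicated(seen)))
})

test_that("simulated movies track without identity errors across seeds", {
  for (seed in 1:5) {
    s <- small_sim(seed = seed, n_frames = 10, n_founders = 2, n_divisions = 1,
                   render = FALSE)
    tr <- track_movie(s$sim$truth$detections, s$spacing)
    lin <- lineage_movie(tr)
    expect_true(forest_matches_truth(lin$forest, s$sim$truth),
                label = paste("seed", seed))
  }
})
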