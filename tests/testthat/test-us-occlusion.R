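make_camera <- function(position = c(0, 0, 100), view = c(0, 0, -1),
                        up = c(0, 1, 0)) {
  camera_pose(position, view, up)
}

test_that("camera placement tracks the spinous apexes and stand-off height", {
  spine <- small_spine()$spine
  cams <- place_cameras(spine, height_mm = 100, sweep_step_mm = 40)
  expect_gte(length(cams), 3L)
  # view directions of a straight-ish sweep are near-parallel
  dirs <- t(vapply(cams, `[[`, numeric(3), "view_dir"))
  expect_lt(max(apply(dirs, 1L, function(d) sum(abs(d - dirs[1L, ])))), 1e-3)
  apexes <- t(vapply(spine$levels, function(m)
    m$vertices[which.max(m$vertices[, 2L]), ], numeric(3)))
  pos <- t(vapply(cams, `[[`, numeric(3), "position"))
  # each apex has a camera at the stand-off height directly posterior
  for (i in seq_len(nrow(apexes))) {
    d <- sqrt(colSums((t(pos) - (apexes[i, ] + c(0, 100, 0)))^2))
    expect_lt(min(d), 1e-6)
  }
  cams2 <- place_cameras(spine, height_mm = 200, sweep_step_mm = 40)
  pos2 <- t(vapply(cams2, `[[`, numeric(3), "position"))
  # doubling the height doubles the camera-to-apex distance for anchor poses
  expect_equal(min(sqrt(colSums((t(pos2) - (apexes[1L, ] + c(0, 200, 0)))^2))),
               0, tolerance = 1e-6)
  # on a straight uniform five-level spine with the sweep step equal to the
  # level pitch, every spinous apex is some pose's nearest apex
  uni <- lapply(1:5, function(i) vertebra_params(seed = 3L, jitter_mm = 0))
  flat <- make_spine(5L, params = uni, lordosis_deg = 0, seed = 3L)$spine
  pitch <- 2 * 13 + 6
  cams5 <- place_cameras(flat, height_mm = 100, sweep_step_mm = pitch)
  expect_gte(length(cams5), 5L)
  apex5 <- t(vapply(flat$levels, function(m)
    m$vertices[which.max(m$vertices[, 2L]), ], numeric(3)))
  pos5 <- t(vapply(cams5, `[[`, numeric(3), "position"))
  nearest <- apply(pos5, 1L, function(p) which.min(colSums((t(apex5) - p)^2)))
  expect_setequal(unique(nearest), 1:5)
  expect_error(place_cameras(spine, height_mm = 0), "positive")
  expect_error(camera_pose(c(0, 0, 0), c(0, 0, 2), c(0, 1, 0)), "unit")
  expect_error(camera_pose(c(0, 0, 0), c(0, 0, 1), c(0, 1e-3, 1)), "orthogonal")
})

test_that("normal and grazing incidence behave as the physics dictates", {
  cam <- make_camera()
  # plane orthogonal to the beam: every ray hits, incidence about 0
  facing <- plane_mesh(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 200, 200)
  hits <- raycast_visible(facing, cam, grid = c(8, 8, 30))
  expect_equal(nrow(hits), 64L)
  # incidence equals each ray's own angle from the beam axis: bounded by the
  # fan's diagonal half-angle (atan(sqrt(2) * tan(15 deg)) ~ 20.8 deg)
  expect_lt(max(hits$incidence_deg), 21)
  expect_lt(min(hits$incidence_deg), 4)
  # plane parallel to the beam: grazing, nothing kept
  parallel <- plane_mesh(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), 200, 200)
  expect_equal(nrow(raycast_visible(parallel, cam, grid = c(8, 8, 30))), 0L)
})

test_that("first-hit shadowing hides geometry behind the first interface", {
  cam <- make_camera()
  near <- box_mesh(c(0, 0, 20), c(60, 60, 5))
  far <- box_mesh(c(0, 0, -40), c(20, 20, 5))
  hits <- raycast_visible(list(near = near, far = far), cam, grid = c(16, 16, 40))
  expect_gt(nrow(hits), 0)
  expect_false("far" %in% hits$source_level)
  # adding an occluder never increases another mesh's retained point count
  alone <- raycast_visible(list(far = far), cam, grid = c(16, 16, 40))
  expect_gte(sum(alone$source_level == "far"), sum(hits$source_level == "far"))
})

test_that("ray casting matches the exhaustive per-face oracle exactly", {
  cam <- make_camera(c(5, -3, 80), c(0, 0, -1), c(0, 1, 0))
  scene <- list(ball = sphere_mesh(25, c(0, 0, 0), 8L, 12L),
                slab = plane_mesh(c(0, -10, 40), c(1, 0, 0), c(0, 1, 0), 18, 6))
  expect_lte(sum(vapply(scene, function(m) nrow(m$faces), integer(1))), 200L)
  grid <- c(24, 24, 50)
  for (max_inc in c(90, 60)) {
    got <- raycast_visible(scene, cam, grid = grid, max_incidence_deg = max_inc)
    fan <- sonocomplete:::ray_fan(cam, grid)
    want <- raycast_oracle(scene, cam, fan$dirs, max_inc)
    expect_identical(sort(got$ray), sort(want$ray))
    o <- order(got$ray); w <- order(want$ray)
    expect_lt(max(abs(got$t[o] - want$t[w])), 1e-9)
    expect_identical(got$source_level[o], want$level[w])
    expect_lt(max(abs(got$incidence_deg[o] - want$incidence[w])), 1e-9)
  }
})

test_that("scattering matches the exhaustive two-scene oracle and shrinks the view", {
  cam <- make_camera(c(0, 0, 90), c(0, 0, -1), c(0, 1, 0))
  block <- box_mesh(c(0, 0, 0), c(40, 30, 20))
  grid <- c(24, 24, 40)
  base <- raycast_visible(block, cam, grid = grid)
  shifted_hits <- apply_scatter(block, cam, shift_mm = 20, grid = grid)
  # subset property and monotone occlusion
  expect_lte(nrow(shifted_hits), nrow(base))
  expect_true(all(shifted_hits$ray %in% base$ray))
  # identity at zero shift
  zero <- apply_scatter(block, cam, shift_mm = 0, grid = grid)
  expect_equal(zero, base)
  # oracle: cast original and both shifted copies exhaustively
  fan <- sonocomplete:::ray_fan(cam, grid)
  orig <- raycast_oracle(list(L1 = block), cam, fan$dirs, 90)
  shift_mesh <- function(m, s) triangle_mesh(sweep(m$vertices, 2L, s, "+"), m$faces)
  copies <- list(p = shift_mesh(block, 20 * fan$right),
                 m = shift_mesh(block, -20 * fan$right))
  cop <- raycast_oracle(copies, cam, fan$dirs, 180)
  keep <- vapply(seq_len(nrow(orig)), function(i) {
    j <- which(cop$ray == orig$ray[i])
    length(j) == 0L || cop$t[j] >= orig$t[i] - 1e-9
  }, logical(1))
  want <- orig[keep, ]
  expect_identical(sort(shifted_hits$ray), sort(want$ray))
})

test_that("incidence threshold is monotone in the kept-point set", {
  spine <- small_spine()$spine
  cam <- place_cameras(spine)[[2L]]
  kept <- lapply(c(40, 70, 90, 180), function(thr)
    raycast_visible(spine, cam, grid = c(24, 24, 60), max_incidence_deg = thr)$ray)
  for (i in seq_len(length(kept) - 1L))
    expect_true(all(kept[[i]] %in% kept[[i + 1L]]))
})

test_that("masking partitions hits by level and errors on empty views", {
  spine <- small_spine()$spine
  cam <- place_cameras(spine)[[2L]]
  hits <- raycast_visible(spine, cam, grid = c(32, 32, 60))
  views <- lapply(intersect(names(spine$levels), hits$source_level),
                  function(lev) mask_by_vertebra(hits, lev))
  total <- sum(vapply(views, function(v) nrow(v$cloud$points), integer(1)))
  expect_equal(total, nrow(hits))
  for (v in views) expect_true(all(v$cloud$labels == v$level))
  only_l1 <- hits[hits$source_level == "L1", ]
  expect_error(mask_by_vertebra(only_l1, "L3"), "empty view")
})

test_that("neighboring cloud fusion adds the seeded boundary-band points", {
  spine <- small_spine()$spine
  cam_list <- place_cameras(spine)
  hits <- do.call(rbind, lapply(cam_list, function(cm)
    raycast_visible(spine, cm, grid = c(32, 32, 60))))
  views <- lapply(names(spine$levels), function(lev) mask_by_vertebra(hits, lev))
  sizes <- vapply(views, function(v) nrow(v$cloud$points), integer(1))

  unchanged <- fuse_neighbors(views, fraction = 0)
  expect_identical(unchanged[[1L]]$cloud$points, views[[1L]]$cloud$points)

  fused <- fuse_neighbors(views, fraction = 0.2, seed = 5L)
  expect_true(all(vapply(fused, `[[`, logical(1), "fusion_applied")))
  # middle view gains round(0.2 * n) from each of its two neighbours
  expect_equal(nrow(fused[[2L]]$cloud$points),
               sizes[2L] + round(0.2 * sizes[1L]) + round(0.2 * sizes[3L]))
  # reproducible under the same seed
  fused2 <- fuse_neighbors(views, fraction = 0.2, seed = 5L)
  expect_identical(fused[[2L]]$cloud$points, fused2[[2L]]$cloud$points)
  # fused points keep their original labels
  expect_setequal(unique(fused[[2L]]$cloud$labels), c("L1", "L2", "L3"))
  # fraction 1 on two views: each contains the union of both clouds
  two <- fuse_neighbors(views[1:2], fraction = 1, seed = 1L)
  expect_equal(nrow(two[[1L]]$cloud$points), sizes[1L] + sizes[2L])
  expect_equal(nrow(two[[2L]]$cloud$points), sizes[1L] + sizes[2L])
})

test_that("dataset generation yields one normalized pair per level, reproducibly", {
  spine <- small_spine()$spine
  cfg <- dataset_config(n_in = 128L, n_gt = 128L, grid = c(48, 48, 60))
  ds <- generate_dataset(spine, cfg, seed = 21L)
  expect_equal(length(ds$pairs), 3L)
  expect_setequal(vapply(ds$pairs, `[[`, character(1), "level"),
                  c("L1", "L2", "L3"))
  for (p in ds$pairs) {
    expect_equal(nrow(p$partial$points), 128L)
    expect_equal(nrow(p$complete$points), 128L)
    # both clouds within the unit sphere + 10% slack
    expect_lte(max(sqrt(rowSums(p$complete$points^2))), 1 + 1e-9)
    expect_lte(max(sqrt(rowSums(p$partial$points^2))), 1.1)
  }
  ds2 <- generate_dataset(spine, cfg, seed = 21L)
  expect_identical(ds$pairs[[2L]]$partial$points, ds2$pairs[[2L]]$partial$points)
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("jitter-free partial clouds lie on the ground-truth surface", {
  spine <- make_spine(n_levels = 3L, seed = 40L,
                      params = lapply(1:3, function(i)
                        vertebra_params(seed = 40L + i, jitter_mm = 0)))$spine
  cfg <- dataset_config(n_in = 96L, n_gt = 96L, shift_mm = 0,
                        fusion_fraction = 0, joint_limit_deg = 0,
                        grid = c(48, 48, 60))
  ds <- generate_dataset(spine, cfg, seed = 3L)
  p <- ds$pairs[[2L]]
  world <- sweep(p$partial$points * p$transform$scale, 2L, p$transform$center, "+")
  lev <- p$level
  d <- sonocomplete:::points_to_mesh_distance(world, spine$levels[[lev]])
  expect_lt(max(d), 1)
})
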