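test_that("vertebra generation is deterministic and validates parameters", {
  a <- make_vertebra(vertebra_params(seed = 7L))
  b <- make_vertebra(vertebra_params(seed = 7L))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_error(vertebra_params(canal_radius = 50), "canal_radius")
  expect_error(vertebra_params(level_scale = 2), "level_scale")
  expect_error(vertebra_params(spinous_length = -1), "positive")
})

test_that("jitter-free vertebrae are exactly mirror-symmetric and connected", {
  m <- make_vertebra(vertebra_params(jitter_mm = 0))
  mirrored <- m$vertices
  mirrored[, 1L] <- -mirrored[, 1L]
  d_fwd <- sqrt(max(sonocomplete:::cpp_nn(mirrored, m$vertices)$d2))
  d_bwd <- sqrt(max(sonocomplete:::cpp_nn(m$vertices, mirrored)$d2))
  expect_lt(max(d_fwd, d_bwd), 1e-6)
  expect_true(mesh_is_connected(m))
})

test_that("body size scales the anterior bounding extent proportionally", {
  base <- make_vertebra(vertebra_params(jitter_mm = 0))
  big <- make_vertebra(vertebra_params(body_radii = 2 * c(22, 16, 13),
                                       canal_radius = 9, jitter_mm = 0))
  # isolate the anterior body: clip everything posterior of the arch
  # (canal radius 9 plus twice the arch tube radius, with margin)
  body_extents <- function(m) {
    v <- m$vertices[m$vertices[, 2L] < -(9 + 2 * 3.5 + 2), , drop = FALSE]
    c(diff(range(v[, 1L])), diff(range(v[, 3L])))
  }
  ratio <- body_extents(big) / body_extents(base)
  expect_lt(max(abs(ratio - 2)), 0.05 * 2)
})

test_that("spines stack cranio-caudally with landmarks on the surface", {
  res <- small_spine()
  expect_s3_class(res$spine, "labeled_spine")
  expect_identical(names(res$spine$levels), c("L1", "L2", "L3"))
  # straight stack of identical vertebrae: collinear centroids
  uni <- lapply(1:3, function(i) vertebra_params(seed = 2L, jitter_mm = 0))
  straight <- make_spine(n_levels = 3L, params = uni, lordosis_deg = 0,
                         seed = 2L)$spine
  cents <- t(vapply(straight$levels, sonocomplete:::mesh_centroid, numeric(3)))
  expect_lt(max(abs(cents[, 1L] - cents[1L, 1L])), 1e-6)
  expect_lt(max(abs(cents[, 2L] - cents[1L, 2L])), 1e-6)
  # spinous crest polylines lie within 1 mm of their mesh surface
  for (lev in names(res$spine$levels)) {
    lm <- attr(res$spine$levels[[lev]], "landmarks")
    d <- sonocomplete:::points_to_mesh_distance(lm$spinous_centerline,
                                                res$spine$levels[[lev]])
    expect_lt(max(d), 1)
  }
  # landmark table covers every level and landmark type
  expect_setequal(unique(res$landmarks$level), c("L1", "L2", "L3"))
  expect_true(all(c("spinous_centerline", "articular_sup_left",
                    "articular_inf_right") %in% res$landmarks$landmark))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_landmarks(res$landmarks, f)
  expect_equal(read_landmarks(f)$x, res$landmarks$x, tolerance = 1e-9)
})

test_that("the posterior arch is visible from above (occlusion tests are non-vacuous)", {
  spine <- small_spine()$spine
  cams <- place_cameras(spine)
  hits <- raycast_visible(spine, cams[[2L]], grid = c(32, 32, 60))
  expect_gt(nrow(hits), 0)
  # the spinous process (posterior-most structure) is among the hits: some
  # hit must be close to the level's posterior apex
  apex_y <- max(spine$levels$L2$vertices[, 2L])
  expect_gt(max(hits$y), apex_y - 10)
})
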