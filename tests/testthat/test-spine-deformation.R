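test_that("the fitted spine curve interpolates the centroids", {
  spine <- small_spine()$spine
  cv <- fit_spine_curve(spine)
  expect_lt(max(abs(cv$eval(cv$knot_s) - cv$knots)), 1e-6)
  ends <- sqrt(sum((cv$knots[nrow(cv$knots), ] - cv$knots[1L, ])^2))
  expect_gte(cv$length, ends - 1e-9)
  # collinear centroids give a straight (zero-curvature) interpolant
  uni <- lapply(1:3, function(i) vertebra_params(seed = 2L, jitter_mm = 0))
  straight <- make_spine(n_levels = 3L, params = uni, lordosis_deg = 0,
                         seed = 2L)$spine
  cs <- fit_spine_curve(straight)
  s <- seq(0, cs$length, length.out = 25L)
  pts <- cs$eval(s)
  # all evaluated points collinear with the end points
  dir <- (cs$knots[3L, ] - cs$knots[1L, ])
  dir <- dir / sqrt(sum(dir^2))
  rel <- sweep(pts, 2L, cs$knots[1L, ])
  off <- rel - outer(drop(rel %*% dir), dir)
  expect_lt(max(abs(off)), 1e-6)
  expect_error(fit_spine_curve(labeled_spine(list(L1 = box_mesh()))), "2 levels")
})

test_that("curvature sampling respects limits, bias and determinism", {
  zero <- sample_curvature("sitting", 0, 4L, seed = 1L)
  expect_identical(zero$rotations_deg, rep(0, 4L))
  a <- sample_curvature("prone", 10, 4L, seed = 5L)
  b <- sample_curvature("prone", 10, 4L, seed = 5L)
  expect_identical(a$rotations_deg, b$rotations_deg)
  many <- unlist(lapply(1:250, function(s)
    sample_curvature("sitting", 10, 4L, seed = s)$rotations_deg))
  expect_lte(max(abs(many)), 10)
  expect_gt(mean(many), 0)   # sitting biases toward flexion
  many_p <- unlist(lapply(1:250, function(s)
    sample_curvature("prone", 10, 4L, seed = s)$rotations_deg))
  expect_lt(mean(many_p), mean(many))
})

test_that("reposing is rigid per vertebra and exactly invertible", {
  spine <- small_spine()$spine
  sample <- sample_curvature("sitting", 8, 2L, seed = 31L)
  bent <- deform_spine(spine, sample)
  # rigidity: pairwise distances of 100 random vertices unchanged to 1e-6
  set.seed(1)
  for (lev in names(spine$levels)) {
    idx <- sample(nrow(spine$levels[[lev]]$vertices), 100L)
    d0 <- dist(spine$levels[[lev]]$vertices[idx, ])
    d1 <- dist(bent$levels[[lev]]$vertices[idx, ])
    expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-9)), 1e-6)
  }
  # identity sample leaves the spine untouched
  id <- sample_curvature("sitting", 0, 2L, seed = 1L)
  same <- deform_spine(spine, id)
  expect_identical(same$levels$L2$vertices, spine$levels$L2$vertices)
  # composition consistency: A then -A returns the original within 1e-5 mm
  neg <- sample
  neg$rotations_deg <- -sample$rotations_deg
  back <- deform_spine(bent, neg)
  for (lev in names(spine$levels))
    expect_lt(max(abs(back$levels[[lev]]$vertices - spine$levels[[lev]]$vertices)),
              1e-5)
  expect_error(deform_spine(spine, sample_curvature("sitting", 5, 3L, seed = 1L)),
               "joints")
})

test_that("a single-joint flexion rotates the distal body axis by that angle", {
  spine <- make_spine(n_levels = 2L, lordosis_deg = 0, seed = 12L)$spine
  sample <- sample_curvature("sitting", 0, 1L, seed = 1L)
  sample$rotations_deg <- 5
  bent <- deform_spine(spine, sample)
  axis_of <- function(mesh) {
    p <- prcomp(mesh$vertices)$rotation[, 1L]
    if (p[which.max(abs(p))] < 0) -p else p
  }
  a0 <- axis_of(spine$levels$L2)
  a1 <- axis_of(bent$levels$L2)
  ang <- acos(min(1, abs(sum(a0 * a1)))) * 180 / pi
  expect_lt(abs(ang - 5), 0.1)
})
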