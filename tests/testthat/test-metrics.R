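test_that("Chamfer distance: identities, closed forms, brute-force oracle", {
  set.seed(11)
  P <- matrix(rnorm(90), 30, 3)
  expect_equal(chamfer(P, P), 0)
  expect_equal(chamfer(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1), scale = 1), 2)
  for (trial in 1:5) {
    A <- matrix(rnorm(3 * sample(5:50, 1)), ncol = 3)
    B <- matrix(rnorm(3 * sample(5:50, 1)), ncol = 3)
    expect_equal(chamfer(A, B), chamfer_oracle(A, B), tolerance = 1e-12)
    expect_equal(chamfer(A, B, squared = FALSE),
                 chamfer_oracle(A, B, squared = FALSE), tolerance = 1e-12)
  }
  expect_error(chamfer(matrix(numeric(0), 0, 3), P), "non-empty")
})

test_that("Chamfer distance obeys symmetry, rigid invariance and the scaling law", {
  set.seed(12)
  A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(45), 15, 3)
  expect_equal(chamfer(A, B), chamfer(B, A))
  R <- sonocomplete:::rotation_about(c(1, 2, 0.5), 0.7)
  t <- c(4, -2, 9)
  cdr <- chamfer(sonocomplete:::transform_points(A, R, t),
                 sonocomplete:::transform_points(B, R, t))
  expect_lt(abs(cdr - chamfer(A, B)) / chamfer(A, B), 1e-6)
  s <- 2.5
  expect_equal(chamfer(s * A, s * B, scale = 1), s^2 * chamfer(A, B, scale = 1),
               tolerance = 1e-9)
})

test_that("EMD: identities, closed form, exhaustive assignment oracle", {
  set.seed(13)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(emd(P, P), 0)
  expect_equal(emd(rbind(c(0, 0, 0), c(2, 0, 0)), rbind(c(1, 0, 0), c(3, 0, 0))), 1)
  for (n in c(5L, 8L, 12L)) {
    A <- matrix(rnorm(3 * n), n, 3); B <- matrix(rnorm(3 * n), n, 3)
    expect_lt(abs(emd(A, B) - emd_oracle(A, B)), 1e-6)
    expect_equal(emd(A, B), emd(B, A), tolerance = 1e-12)
  }
  expect_error(emd(P, P[1:5, ]), "cardinalities")
})

test_that("F-score: identities, closed form, symmetry of the harmonic mean", {
  set.seed(14)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(unname(fscore(P, P, 0.5)), c(1, 1, 1))
  far <- sweep(P, 2L, c(100, 0, 0), "+")
  expect_equal(unname(fscore(P, far, 1)), c(0, 0, 0))
  fs <- fscore(rbind(c(0, 0, 0), c(5, 0, 0)), matrix(c(0, 0, 0), 1), 1)
  expect_equal(unname(fs), c(0.5, 1, 2 / 3))
  swapped <- fscore(matrix(c(0, 0, 0), 1), rbind(c(0, 0, 0), c(5, 0, 0)), 1)
  expect_equal(fs[["f1"]], swapped[["f1"]])
  expect_equal(fs[["precision"]], swapped[["recall"]])
})

test_that("spinous-process centerline distance densifies and is order-invariant", {
  line <- function(y0) cbind(seq(0, 20, length.out = 5L), y0, 0)
  a <- centerline_annotation(line(0), "input")
  b <- centerline_annotation(line(0), "completion")
  expect_equal(sp_centerline_cd(a, b), 0)
  # parallel lines offset by eps: squared CD = 2 * eps^2 (both directions)
  eps <- 0.8
  c2 <- centerline_annotation(line(eps), "completion")
  got <- sp_centerline_cd(a, c2, scale = 1)
  expect_lt(abs(got - 2 * eps^2) / (2 * eps^2), 0.01)
  rev <- centerline_annotation(line(eps)[5:1, ], "completion")
  expect_equal(sp_centerline_cd(a, rev, scale = 1), got)
  expect_error(centerline_annotation(matrix(c(0, 0, 0), 1), "input"), "2 points")
  expect_error(centerline_annotation(rbind(c(0, 0, 0), c(0, 0, 0)), "input"),
               "distinct")
})

test_that("facet distances pair by level and side", {
  a <- facet_landmark("L2", "left", c(0, 0, 0))
  b <- facet_landmark("L2", "left", c(3, 4, 0))
  expect_equal(facet_distance(a, b), 5)
  expect_equal(facet_distance(a, a), 0)
  expect_error(facet_distance(a, facet_landmark("L2", "right", c(0, 0, 0))),
               "mismatch")
  expect_error(facet_distance(a, facet_landmark("L3", "left", c(0, 0, 0))),
               "mismatch")
})

test_that("report aggregation is consistent with its rows", {
  rows <- data.frame(level = c("L1", "L2", "L3"),
                     cd_scaled = c(2, 4, 9),
                     f1 = c(0.5, 0.7, 0.9),
                     facet_left_mm = c(1, 6, 2),
                     facet_right_mm = c(2, 8, 3))
  rep <- summarize_metrics(rows)
  agg <- rep$aggregate
  expect_equal(agg$cd_scaled, c(mean(rows$cd_scaled), median(rows$cd_scaled)))
  expect_equal(agg$f1[1L], mean(rows$f1))
  expect_identical(unname(rep$facet_acceptable), c(TRUE, FALSE, TRUE))
  expect_equal(rep$n_acceptable, 2L)
  # missing entries are skipped, not propagated
  rows$facet_left_mm[2L] <- NA
  rep2 <- summarize_metrics(rows)
  expect_equal(rep2$aggregate$facet_left_mm[1L], mean(c(1, 2)))
  expect_equal(rep2$n_acceptable, 2L)
})
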