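test_that("mesh formats round-trip vertex coordinates", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                       rbind(c(1L, 2L, 3L)))
  for (fmt in c("ply", "obj", "stl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(tri, f)
    back <- read_mesh(f)
    expect_equal(nrow(back$vertices), 3L)
    expect_equal(nrow(back$faces), 1L)
    expect_lt(max(abs(back$vertices - tri$vertices)), 1e-5)
  }
})

test_that("ASCII and binary PLY of the same mesh agree", {
  m <- box_mesh(size = c(3, 5, 7))
  fa <- withr::local_tempfile(fileext = ".ply")
  fb <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, fa, binary = FALSE)
  write_mesh(m, fb, binary = TRUE)
  a <- read_mesh(fa); b <- read_mesh(fb)
  expect_equal(a$vertices, b$vertices, tolerance = 1e-12)
  expect_identical(a$faces, b$faces)
  expect_lt(max(abs(a$vertices - m$vertices)), 1e-10)
})

test_that("malformed mesh input is rejected with diagnostics", {
  expect_error(read_mesh(tempfile(fileext = ".ply")), "not found")
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "3 0 1 2"), f)
  expect_error(read_mesh(f), "index")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1L, 1L, 2L))),
               "degenerate")
})

test_that("point clouds round-trip through PLY with labels, XYZ without", {
  set.seed(4)
  pc <- point_cloud(matrix(rnorm(30, sd = 40), 10, 3),
                    normals = matrix(rep(c(1, 0, 0), each = 10), 10, 3),
                    labels = rep(c("L1", "L2"), 5))
  for (bin in c(FALSE, TRUE)) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_pointcloud(pc, f, binary = bin)
    back <- read_pointcloud(f)
    expect_lt(max(abs(back$points - pc$points)), 1e-5)
    expect_identical(back$labels, pc$labels)
  }
  fx <- withr::local_tempfile(fileext = ".xyz")
  write_pointcloud(pc, fx)
  bx <- read_pointcloud(fx)
  expect_lt(max(abs(bx$points - pc$points)), 1e-5)
  expect_null(bx$labels)
  expect_error(write_pointcloud(point_cloud(matrix(numeric(0), 0, 3)),
                                withr::local_tempfile(fileext = ".ply")),
               "empty")
})

test_that("label volumes become cranio-caudally ordered spines in world mm", {
  arr <- array(0L, c(24L, 24L, 40L))
  arr[9:16, 9:16, 5:12] <- 20L     # cube 1
  arr[9:16, 9:16, 25:32] <- 21L    # cube 2, stacked along z
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 3)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)

  spine <- labelvolume_to_spine(f, c(L1 = 20L, L2 = 21L))
  expect_s3_class(spine, "labeled_spine")
  expect_identical(names(spine$levels), c("L1", "L2"))
  # centroid within 0.6 voxel of the cube center
  cent <- sonocomplete:::mesh_centroid(spine$levels$L1)
  expect_lt(max(abs(cent - c(11.5, 11.5, 7.5 * 3))), 0.6 * 3)
  # anisotropic affine: extent along third axis = voxel count * spacing
  bb <- sonocomplete:::mesh_bbox(spine$levels$L2)
  expect_equal(unname(bb[2L, ] - bb[1L, ]), c(8, 8, 24), tolerance = 1e-9)
  expect_error(labelvolume_to_spine(f, c(L1 = 99L)), "99.*absent|absent")
})

test_that("unit-sphere normalization is invertible, translation-invariant and idempotent", {
  set.seed(9)
  pts <- matrix(rnorm(600, sd = 25), 200, 3)
  pc <- point_cloud(pts)
  nrm <- normalize_cloud(pc)
  expect_lt(max(abs(colMeans(nrm$cloud$points))), 1e-9)
  expect_equal(max(sqrt(rowSums(nrm$cloud$points^2))), 1, tolerance = 1e-12)
  back <- denormalize_cloud(nrm$cloud, nrm$transform)
  expect_lt(max(abs(back$points - pts)) / max(abs(pts)), 1e-6)
  shifted <- normalize_cloud(point_cloud(sweep(pts, 2L, c(100, 0, 0), "+")))
  expect_lt(max(abs(shifted$cloud$points - nrm$cloud$points)), 1e-9)
  twice <- normalize_cloud(nrm$cloud)
  expect_lt(max(abs(twice$cloud$points - nrm$cloud$points)), 1e-6)
  expect_error(normalize_cloud(point_cloud(matrix(1, 5, 3))), "degenerate")
})
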