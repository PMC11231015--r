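#' Triangle mesh
#'
#' A triangle surface in world millimetres: an `n x 3` vertex matrix, an
#' `m x 3` integer face matrix (1-based vertex indices) and optional unit
#' vertex normals. Faces must index existing vertices and may not repeat a
#' vertex; normals, when present, must be unit length.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle (1-based indices).
#' @param normals optional numeric matrix of per-vertex unit normals.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as_xyz(vertices, "vertices")
  faces <- as_face_matrix(faces)
  if (nrow(faces) > 0L) {
    if (max(faces) > nrow(vertices) || min(faces) < 1L)
      stop("face index out of range: faces must reference existing vertices")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
              faces[, 2L] == faces[, 3L]))
      stop("degenerate face: a triangle repeats a vertex")
  }
  if (!is.null(normals)) {
    normals <- as_xyz(normals, "normals")
    if (nrow(normals) != nrow(vertices))
      stop("normals must have one row per vertex")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("vertex normals must be unit length (within 1e-6)")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

#' Point cloud
#'
#' A set of 3D points in millimetres with optional unit normals and optional
#' per-point vertebra level labels (`"L1"` .. `"L5"`).
#'
#' @param points numeric matrix, one row per point.
#' @param normals optional per-point unit normals.
#' @param labels optional character vector of level tags, one per point.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, labels = NULL) {
  points <- as_xyz(points, "points")
  if (any(!is.finite(points))) stop("points must be finite")
  if (!is.null(normals)) {
    normals <- as_xyz(normals, "normals")
    if (nrow(normals) != nrow(points))
      stop("normals must have the same cardinality as points")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(points))
      stop("labels must have the same cardinality as points")
  }
  structure(list(points = points, normals = normals, labels = labels),
            class = "point_cloud")
}

#' Labeled spine
#'
#' An ordered cranio-caudal sequence of vertebra meshes. Levels must be
#' unique, ordered L1 first, and their body centroids strictly ordered along
#' the cranio-caudal axis (taken as the direction of largest centroid spread).
#'
#' @param levels named list of [triangle_mesh()] objects; names are level
#'   tags such as `"L1"`.
#' @return an object of class `labeled_spine`.
#' @export
labeled_spine <- function(levels) {
  if (is.null(names(levels)) || anyDuplicated(names(levels)))
    stop("levels must be uniquely named")
  ok <- vapply(levels, inherits, logical(1), "triangle_mesh")
  if (!all(ok)) stop("every level must be a triangle_mesh")
  if (length(levels) >= 2L) {
    cents <- t(vapply(levels, mesh_centroid, numeric(3)))
    axis <- prcomp(cents, center = TRUE)$rotation[, 1L]
    proj <- drop(cents %*% axis)
    if (!(all(diff(proj) > 0) || all(diff(proj) < 0)))
      stop("vertebral body centroids are not strictly ordered cranio-caudally")
  }
  structure(list(levels = levels), class = "labeled_spine")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else ", with normals",
              if (is.null(x$labels)) "" else
                sprintf(", labels {%s}", paste(unique(x$labels), collapse = ","))))
  invisible(x)
}

#' @export
print.labeled_spine <- function(x, ...) {
  cat(sprintf("labeled_spine: %d levels (%s)\n", length(x$levels),
              paste(names(x$levels), collapse = ", ")))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

as_xyz <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

as_face_matrix <- function(f) {
  f <- as.matrix(f)
  if (ncol(f) != 3L) stop("faces must have 3 columns")
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  f
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

mesh_bbox <- function(mesh) {
  rbind(apply(mesh$vertices, 2L, min), apply(mesh$vertices, 2L, max))
}

cloud_bbox <- function(points) rbind(apply(points, 2L, min), apply(points, 2L, max))

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, angle) {
  axis <- unit(axis)
  K <- matrix(c(0, -axis[3L], axis[2L],
                axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transform_points <- function(points, R = diag(3L), t = c(0, 0, 0)) {
  sweep(points %*% t(R), 2L, t, "+")
}

transform_mesh <- function(mesh, R = diag(3L), t = c(0, 0, 0)) {
  normals <- if (is.null(mesh$normals)) NULL else mesh$normals %*% t(R)
  triangle_mesh(transform_points(mesh$vertices, R, t), mesh$faces, normals)
}

# Area-weighted uniform sampling of a mesh surface (seeded by caller's RNG).
sample_mesh_surface <- function(mesh, n) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  cr <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (sum(area) <= 0) stop("mesh has zero surface area")
  fi <- sample.int(nrow(f), n, replace = TRUE, prob = area)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  pts <- a[fi, , drop = FALSE] * w1 + b[fi, , drop = FALSE] * w2 +
    cc[fi, , drop = FALSE] * w3
  pts
}

# Unsigned distance from points to a mesh surface (exact point-triangle).
points_to_mesh_distance <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- rep(Inf, nrow(points))
  for (k in seq_len(nrow(f))) {
    tri <- v[f[k, ], , drop = FALSE]
    d <- pmin(d, point_triangle_distance(points, tri))
  }
  d
}

# Vectorized point-to-single-triangle distance (Eberly's region method,
# reduced: project onto plane, clamp barycentrics, fall back to edges).
point_triangle_distance <- function(points, tri) {
  a <- tri[1L, ]; b <- tri[2L, ]; cc <- tri[3L, ]
  ab <- b - a; ac <- cc - a
  n <- cross3(ab, ac)
  nn <- sum(n^2)
  p <- sweep(points, 2L, a)
  if (nn < 1e-30) {  # degenerate: use vertices
    d2 <- pmin(rowSums(p^2),
               rowSums(sweep(points, 2L, b)^2),
               rowSums(sweep(points, 2L, cc)^2))
    return(sqrt(d2))
  }
  d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
  d20 <- p %*% ab; d21 <- p %*% ac
  denom <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / denom
  w <- (d00 * d21 - d01 * d20) / denom
  inside <- u >= 0 & w >= 0 & (u + w) <= 1
  # distance via plane for inside points
  dist2 <- rep(Inf, nrow(points))
  if (any(inside)) {
    h <- (p[inside, , drop = FALSE] %*% n) / sqrt(nn)
    dist2[inside] <- h^2
  }
  out <- !inside
  if (any(out)) {
    q <- points[out, , drop = FALSE]
    dist2[out] <- pmin(point_segment_distance2(q, a, b),
                       point_segment_distance2(q, b, cc),
                       point_segment_distance2(q, cc, a))
  }
  sqrt(pmax(dist2, 0))
}

point_segment_distance2 <- function(points, s0, s1) {
  d <- s1 - s0
  l2 <- sum(d^2)
  p <- sweep(points, 2L, s0)
  t <- if (l2 < 1e-30) rep(0, nrow(points)) else pmin(1, pmax(0, (p %*% d) / l2))
  proj <- outer(drop(t), d)
  rowSums((p - proj)^2)
}
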