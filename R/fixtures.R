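#' Parameters of a procedural lumbar vertebra
#'
#' The fixture vertebra is a stylized lumbar vertebra assembled from smooth
#' implicit primitives in a local frame with x pointing left-right (sagittal
#' mirror plane x = 0), +y posterior and +z cranial, all lengths in mm:
#' an ellipsoidal body (anterior), a toroidal arch enclosing the spinal
#' canal, a caudally angled tapered spinous process on the posterior midline,
#' two lateral transverse processes and four articular prominences whose
#' centers are emitted as facet-joint ground truth.
#'
#' @param body_radii three semi-axes of the vertebral body (mm).
#' @param canal_radius radius of the spinal canal (mm); must be smaller than
#'   the smallest body semi-axis.
#' @param spinous_length length of the spinous process (mm).
#' @param spinous_caudal_angle caudal tilt of the spinous process (degrees).
#' @param transverse_length length of each transverse process (mm).
#' @param articular_offset lateral offset of the articular prominences (mm).
#' @param level_scale per-level size multiplier in `[0.8, 1.3]`.
#' @param seed integer seed for the vertex jitter.
#' @param jitter_mm amplitude of random vertex jitter (mm; 0 disables).
#' @param voxel_mm meshing resolution (mm).
#' @return a validated parameter list of class `vertebra_params`.
#' @export
vertebra_params <- function(body_radii = c(22, 16, 13),
                            canal_radius = 9,
                            spinous_length = 30,
                            spinous_caudal_angle = 25,
                            transverse_length = 22,
                            articular_offset = 13,
                            level_scale = 1,
                            seed = 1L,
                            jitter_mm = 0.2,
                            voxel_mm = 2) {
  p <- list(body_radii = as.numeric(body_radii), canal_radius = canal_radius,
            spinous_length = spinous_length,
            spinous_caudal_angle = spinous_caudal_angle,
            transverse_length = transverse_length,
            articular_offset = articular_offset, level_scale = level_scale,
            seed = as.integer(seed), jitter_mm = jitter_mm, voxel_mm = voxel_mm)
  lens <- c(p$body_radii, p$canal_radius, p$spinous_length,
            p$transverse_length, p$articular_offset, p$voxel_mm)
  if (any(lens <= 0)) stop("all vertebra lengths must be positive")
  if (p$canal_radius >= min(p$body_radii))
    stop("canal_radius must be smaller than the smallest body semi-axis")
  if (p$level_scale < 0.8 || p$level_scale > 1.3)
    stop("level_scale must lie in [0.8, 1.3]")
  if (p$jitter_mm < 0) stop("jitter_mm must be non-negative")
  structure(p, class = "vertebra_params")
}

# Geometric layout derived from (scaled) parameters. The canal center is the
# local origin; the body sits anterior (-y), the arch is a torus around the
# canal whose anterior segment is embedded in the body (guaranteeing a
# connected union), the spinous process grows posteriorly and caudally.
vertebra_layout <- function(params) {
  s <- params$level_scale
  br <- params$body_radii * s
  canal <- params$canal_radius * s
  tube <- max(3.5 * s, 0.35 * canal)        # arch tube radius
  ring <- canal + tube                      # arch ring radius
  body_center <- c(0, -(ring + 0.55 * br[2L]), 0)
  ang <- params$spinous_caudal_angle * pi / 180
  sp_start <- c(0, ring, 0.15 * br[3L])
  sp_dir <- c(0, cos(ang), -sin(ang))
  sp_end <- sp_start + params$spinous_length * s * sp_dir
  sp_r0 <- 4.5 * s; sp_r1 <- 2.5 * s
  tp_r <- 3 * s
  tp_start <- list(c(-0.85 * ring, 0, 0), c(0.85 * ring, 0, 0))
  tp_end <- list(c(-(0.85 * ring + params$transverse_length * s), 3 * s, 0),
                 c(0.85 * ring + params$transverse_length * s, 3 * s, 0))
  ap_r <- 4 * s
  ao <- params$articular_offset * s
  z_ap <- 0.85 * br[3L]
  ap_centers <- rbind(sup_left = c(-ao, 0.35 * ring, z_ap),
                      sup_right = c(ao, 0.35 * ring, z_ap),
                      inf_left = c(-ao, 0.35 * ring, -z_ap),
                      inf_right = c(ao, 0.35 * ring, -z_ap))
  # pars-like struts anchor each articular prominence to the arch
  strut_starts <- lapply(1:4, function(i) {
    c(sign(ap_centers[i, 1L]) * 0.75 * ring, 0.25 * ring, 0)
  })
  list(body_radii = br, body_center = body_center, canal = canal,
       tube = tube, ring = ring,
       sp_start = sp_start, sp_end = sp_end, sp_r0 = sp_r0, sp_r1 = sp_r1,
       tp_r = tp_r, tp_start = tp_start, tp_end = tp_end,
       ap_r = ap_r, ap_centers = ap_centers,
       strut_r = 2.5 * s, strut_starts = strut_starts)
}

# Implicit field of the vertebra (negative inside), vectorized over an n x 3
# point matrix. Union = pointwise minimum of the member fields.
vertebra_field <- function(p, layout) {
  L <- layout
  # ellipsoidal body (scaled-radius approximation of the SDF)
  q <- sweep(p, 2L, L$body_center)
  k <- sqrt(q[, 1L]^2 / L$body_radii[1L]^2 + q[, 2L]^2 / L$body_radii[2L]^2 +
              q[, 3L]^2 / L$body_radii[3L]^2)
  f <- (k - 1) * min(L$body_radii)
  # toroidal arch around the canal (ring in the x-y plane, axis z)
  rad <- sqrt(p[, 1L]^2 + p[, 2L]^2)
  f <- pmin(f, sqrt((rad - L$ring)^2 + p[, 3L]^2) - L$tube)
  # tapered spinous process (capsule with linearly varying radius)
  f <- pmin(f, capsule_field(p, L$sp_start, L$sp_end, L$sp_r0, L$sp_r1))
  # transverse processes
  for (i in 1:2)
    f <- pmin(f, capsule_field(p, L$tp_start[[i]], L$tp_end[[i]], L$tp_r, 0.7 * L$tp_r))
  # articular prominences, each tied to the arch by a strut
  for (i in 1:4) {
    q <- sweep(p, 2L, L$ap_centers[i, ])
    f <- pmin(f, sqrt(rowSums(q^2)) - L$ap_r)
    f <- pmin(f, capsule_field(p, L$strut_starts[[i]], L$ap_centers[i, ],
                               L$strut_r, L$strut_r))
  }
  f
}

capsule_field <- function(p, a, b, r0, r1) {
  d <- b - a
  l2 <- sum(d^2)
  q <- sweep(p, 2L, a)
  t <- pmin(1, pmax(0, (q %*% d) / l2))
  closest <- outer(drop(t), d)
  sqrt(rowSums((q - closest)^2)) - (r0 + (r1 - r0) * drop(t))
}

#' Generate a procedural vertebra mesh
#'
#' Evaluates the implicit vertebra on a regular grid (mirror-symmetric about
#' x = 0), extracts the 0-level surface by voxel-boundary meshing, projects
#' every vertex onto the analytic surface by damped Newton steps, and
#' finally applies seeded Gaussian vertex jitter. With `jitter_mm = 0` the
#' mesh is exactly sagittally mirror-symmetric.
#'
#' Construction-time landmarks are attached as `attr(mesh, "landmarks")`:
#' `spinous_centerline` (a polyline on the posterior crest of the spinous
#' process) and `articular_centers` (the four prominence centers, the
#' fixture's facet-joint ground truth).
#'
#' @param params a [vertebra_params()].
#' @return a [triangle_mesh()] with a `landmarks` attribute.
#' @export
make_vertebra <- function(params = vertebra_params()) {
  stopifnot(inherits(params, "vertebra_params"))
  L <- vertebra_layout(params)
  h <- params$voxel_mm
  # symmetric grid in x; generous padding so the surface never touches it
  pad <- 2.5 * h
  xmax <- max(abs(c(L$tp_end[[2L]][1L], L$body_radii[1L], L$ap_centers[, 1L] + L$ap_r))) + pad
  nx <- ceiling(xmax / h)
  xs <- seq(-nx, nx) * h
  ymin <- L$body_center[2L] - L$body_radii[2L] - pad
  ymax <- max(L$sp_end[2L] + L$sp_r0, L$ring + L$tube) + pad
  ys <- seq(floor(ymin / h), ceiling(ymax / h)) * h
  zmin <- min(-L$body_radii[3L] + L$body_center[3L], L$sp_end[3L] - L$sp_r0,
              L$ap_centers[3L, 3L] - L$ap_r) - pad
  zmax <- max(L$body_radii[3L], L$ap_centers[1L, 3L] + L$ap_r, L$ring + L$tube) + pad
  zs <- seq(floor(zmin / h), ceiling(zmax / h)) * h
  grid_pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  f <- vertebra_field(grid_pts, L)
  mask <- array(f < 0, dim = c(length(xs), length(ys), length(zs)))
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(rep(h, 3L))
  affine[1:3, 4L] <- c(xs[1L], ys[1L], zs[1L])
  mesh <- cuberille_mesh(mask, affine)
  v <- project_to_field(mesh$vertices, function(p) vertebra_field(p, L), h)
  if (params$jitter_mm > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(params$seed)
    v <- v + matrix(rnorm(length(v), sd = params$jitter_mm), nrow(v), 3L)
  }
  mesh <- triangle_mesh(v, mesh$faces)
  attr(mesh, "landmarks") <- list(
    spinous_centerline = spinous_crest(L, n = 12L),
    articular_centers = L$ap_centers)
  attr(mesh, "layout") <- L
  mesh
}

# Damped Newton projection of points onto the zero level set of a field.
project_to_field <- function(pts, field_fn, h, iters = 4L) {
  eps <- 1e-3
  for (it in seq_len(iters)) {
    f0 <- field_fn(pts)
    # central differences keep the projection exactly mirror-symmetric for
    # mirror-symmetric fields
    gx <- (field_fn(sweep(pts, 2L, c(eps, 0, 0), "+")) -
             field_fn(sweep(pts, 2L, c(-eps, 0, 0), "+"))) / (2 * eps)
    gy <- (field_fn(sweep(pts, 2L, c(0, eps, 0), "+")) -
             field_fn(sweep(pts, 2L, c(0, -eps, 0), "+"))) / (2 * eps)
    gz <- (field_fn(sweep(pts, 2L, c(0, 0, eps), "+")) -
             field_fn(sweep(pts, 2L, c(0, 0, -eps), "+"))) / (2 * eps)
    g2 <- gx^2 + gy^2 + gz^2
    step <- f0 / pmax(g2, 1e-9)
    step <- sign(step) * pmin(abs(step), h)  # never jump more than one voxel
    pts <- pts - cbind(step * gx, step * gy, step * gz)
  }
  pts
}

# Polyline along the posterior crest of the spinous process, exactly on the
# capsule surface (offset from the axis by the local radius, in-plane).
spinous_crest <- function(L, n = 12L) {
  u <- unit(L$sp_end - L$sp_start)
  d <- c(0, -u[3L], u[2L])          # perpendicular to the axis, sagittal plane
  if (d[2L] < 0) d <- -d            # pick the posterior side
  t <- seq(0.05, 0.95, length.out = n)
  axis_pts <- outer(1 - t, L$sp_start) + outer(t, L$sp_end)
  r <- L$sp_r0 + (L$sp_r1 - L$sp_r0) * t
  axis_pts + outer(r, d)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Generate a procedural five-level lumbar spine
#'
#' Vertebrae are stacked cranio-caudally (L1 first, descending -z) along a
#' circular arc of total sagittal angle `lordosis_deg`, with `gap_mm` of
#' inter-vertebral spacing, each vertebra rigidly rotated to follow the arc
#' tangent. Returns the spine together with a construction-time landmark
#' table (spinous-process crest polylines and the four articular-prominence
#' centers per level) in world coordinates.
#'
#' @param n_levels number of vertebrae (default 5, labeled L1..L5).
#' @param params list of [vertebra_params()], one per level; by default
#'   levels grow mildly in size caudally.
#' @param lordosis_deg total sagittal arc angle (degrees; 0 = straight stack).
#' @param gap_mm inter-vertebral gap (mm).
#' @param seed integer seed (controls per-vertebra jitter).
#' @return list with `spine` (a [labeled_spine()]) and `landmarks` (data
#'   frame: level, landmark, index, x, y, z).
#' @export
make_spine <- function(n_levels = 5L, params = NULL, lordosis_deg = 15,
                       gap_mm = 6, seed = 1L) {
  if (n_levels < 1L) stop("n_levels must be at least 1")
  if (is.null(params)) {
    scales <- if (n_levels == 1L) 1 else seq(0.92, 1.08, length.out = n_levels)
    params <- lapply(seq_len(n_levels), function(i)
      vertebra_params(level_scale = scales[i], seed = seed + i))
  }
  stopifnot(length(params) == n_levels)
  meshes <- lapply(params, make_vertebra)
  heights <- vapply(params, function(p) 2 * p$body_radii[3L] * p$level_scale, numeric(1))
  pitches <- (heights[-n_levels] + heights[-1L]) / 2 + gap_mm
  total_angle <- lordosis_deg * pi / 180
  # per-level tangent angle, centered so the middle of the stack is upright
  angles <- if (n_levels == 1L) 0 else
    total_angle * (seq_len(n_levels) - (n_levels + 1) / 2) / (n_levels - 1)
  centers <- matrix(0, n_levels, 3L)
  for (i in seq_len(n_levels - 1L)) {
    mid <- (angles[i] + angles[i + 1L]) / 2
    step <- rotation_about(c(1, 0, 0), mid) %*% c(0, 0, -pitches[i])
    centers[i + 1L, ] <- centers[i, ] + drop(step)
  }
  out_meshes <- list()
  landmark_rows <- list()
  body_centers <- matrix(0, n_levels, 3L)
  body_radii_w <- matrix(0, n_levels, 3L)
  for (i in seq_len(n_levels)) {
    R <- rotation_about(c(1, 0, 0), angles[i])
    lev <- paste0("L", i)
    lm <- attr(meshes[[i]], "landmarks")
    lay <- attr(meshes[[i]], "layout")
    # the arc positions are the vertebral BODY centers (the bodies form the
    # load-bearing column), so the local body-center offset is subtracted
    t <- centers[i, ] - drop(R %*% lay$body_center)
    m <- transform_mesh(meshes[[i]], R, t)
    crest_w <- transform_points(lm$spinous_centerline, R, t)
    ap_w <- transform_points(lm$articular_centers, R, t)
    rownames(ap_w) <- rownames(lm$articular_centers)
    attr(m, "landmarks") <- list(spinous_centerline = crest_w, articular_centers = ap_w)
    out_meshes[[lev]] <- m
    body_centers[i, ] <- centers[i, ]
    body_radii_w[i, ] <- lay$body_radii
    landmark_rows[[length(landmark_rows) + 1L]] <- data.frame(
      level = lev, landmark = "spinous_centerline",
      index = seq_len(nrow(crest_w)),
      x = crest_w[, 1L], y = crest_w[, 2L], z = crest_w[, 3L])
    landmark_rows[[length(landmark_rows) + 1L]] <- data.frame(
      level = lev, landmark = paste0("articular_", rownames(ap_w)),
      index = 1L, x = ap_w[, 1L], y = ap_w[, 2L], z = ap_w[, 3L])
  }
  # reject placements whose vertebral bodies interpenetrate
  for (i in seq_len(n_levels - 1L)) {
    gap <- sqrt(sum((body_centers[i + 1L, ] - body_centers[i, ])^2))
    if (gap < 0.98 * (body_radii_w[i, 3L] + body_radii_w[i + 1L, 3L]))
      stop(sprintf("placement error: vertebral bodies of L%d and L%d overlap", i, i + 1L))
  }
  list(spine = labeled_spine(out_meshes),
       landmarks = do.call(rbind, landmark_rows))
}

#' Write a landmark table as a plain-text sidecar file
#'
#' @param landmarks data frame as returned by [make_spine()].
#' @param path output path (tab-separated: level, landmark, index, x, y, z).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  write.table(landmarks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landmark sidecar file
#'
#' @param path path written by [write_landmarks()].
#' @return data frame.
#' @export
read_landmarks <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
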