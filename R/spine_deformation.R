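#' Fit a smooth curve through the vertebral body centroids
#'
#' Natural cubic spline interpolation of the centroid sequence against
#' cumulative chord length, re-parameterized by arc length. The interpolant
#' passes through every centroid; for collinear centroids it is exactly the
#' straight line (zero curvature).
#'
#' @param spine a [labeled_spine()] with at least two levels.
#' @return object of class `spine_curve`: list with `knots` (centroids),
#'   `eval(s)` mapping arc length in `[0, length]` to 3D points,
#'   `knot_s` (arc length of each centroid) and `length`.
#' @export
fit_spine_curve <- function(spine) {
  stopifnot(inherits(spine, "labeled_spine"))
  cents <- t(vapply(spine$levels, mesh_centroid, numeric(3)))
  n <- nrow(cents)
  if (n < 2L) stop("need at least 2 levels to fit a spine curve")
  chord <- c(0, cumsum(sqrt(rowSums(diff(cents)^2))))
  fns <- lapply(1:3, function(k)
    stats::splinefun(chord, cents[, k], method = "natural"))
  eval_chord <- function(s) cbind(fns[[1L]](s), fns[[2L]](s), fns[[3L]](s))
  # arc-length reparameterization via dense resampling; the knot chord values
  # are nodes of the piecewise-linear arc<->chord maps, so the interpolant is
  # exact at the centroids
  s_dense <- sort(unique(c(seq(0, max(chord), length.out = 40L * n), chord)))
  pts <- eval_chord(s_dense)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- max(arc)
  chord_of_arc <- stats::approxfun(arc, s_dense, rule = 2L)
  knot_s <- arc[match(chord, s_dense)]
  structure(list(knots = cents,
                 eval = function(s) eval_chord(chord_of_arc(s)),
                 eval_chord = eval_chord,
                 knot_s = knot_s, knot_chord = chord, length = total),
            class = "spine_curve")
}

#' Sample a physiologically constrained curvature
#'
#' Per-joint sagittal rotations are drawn from a truncated normal
#' distribution within `[-limit, limit]` degrees. The sitting posture (the
#' typical pose for visualizing the interlaminar space) biases toward
#' flexion (posterior convexity, positive angles); prone biases toward mild
#' extension. Deterministic per seed.
#'
#' @param posture `"sitting"` or `"prone"`.
#' @param limit_deg positive per-joint limit (degrees); 0 yields the
#'   identity sample.
#' @param n_joints number of inter-vertebral joints.
#' @param seed integer seed.
#' @return object of class `curvature_sample`.
#' @export
sample_curvature <- function(posture = c("sitting", "prone"), limit_deg = 10,
                             n_joints = 4L, seed = 1L) {
  posture <- match.arg(posture)
  if (limit_deg < 0) stop("limit_deg must be non-negative")
  if (limit_deg == 0) {
    rot <- rep(0, n_joints)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    mu <- if (posture == "sitting") limit_deg / 3 else -limit_deg / 6
    sdv <- limit_deg / 2.5
    lo <- stats::pnorm(-limit_deg, mu, sdv)
    hi <- stats::pnorm(limit_deg, mu, sdv)
    rot <- stats::qnorm(runif(n_joints, lo, hi), mu, sdv)
  }
  structure(list(posture = posture, rotations_deg = rot,
                 limit_deg = limit_deg, seed = as.integer(seed)),
            class = "curvature_sample")
}

#' Rigidly repose a spine along a sampled curvature
#'
#' Joint `j` rotates all vertebrae caudal to it by the sampled sagittal
#' angle about a pivot rigidly attached to the joint's cranial vertebra (its
#' body centroid); per-joint rotations accumulate down the chain, so each
#' vertebra moves by a single rigid transform and intra-vertebra distances
#' are preserved exactly. Deforming by a sample and then by its negation
#' restores the original spine. A bounding-volume check rejects poses in
#' which adjacent vertebrae interpenetrate (the caller then resamples).
#'
#' @param spine a [labeled_spine()].
#' @param sample a [sample_curvature()] result with `level count - 1` joints.
#' @return the reposed [labeled_spine()].
#' @export
deform_spine <- function(spine, sample) {
  stopifnot(inherits(spine, "labeled_spine"), inherits(sample, "curvature_sample"))
  n <- length(spine$levels)
  if (length(sample$rotations_deg) != n - 1L)
    stop(sprintf("sample has %d joints but the spine has %d levels",
                 length(sample$rotations_deg), n))
  cents <- t(vapply(spine$levels, mesh_centroid, numeric(3)))
  R <- diag(3L); t <- c(0, 0, 0)
  out <- spine$levels
  for (i in seq_len(n)) {
    if (i > 1L) {
      th <- sample$rotations_deg[i - 1L] * pi / 180
      Rj <- rotation_about(c(1, 0, 0), th)
      pivot <- cents[i - 1L, ]
      # M_i = M_{i-1} o Rot(pivot, th)
      t <- drop(R %*% (pivot - Rj %*% pivot)) + t
      R <- R %*% Rj
    }
    m <- out[[i]]
    lm <- attr(m, "landmarks")
    m <- transform_mesh(m, R, t)
    if (!is.null(lm)) {
      lm$spinous_centerline <- transform_points(lm$spinous_centerline, R, t)
      ap <- transform_points(lm$articular_centers, R, t)
      rownames(ap) <- rownames(lm$articular_centers)
      lm$articular_centers <- ap
      attr(m, "landmarks") <- lm
    }
    out[[i]] <- m
  }
  # bounding-volume interpenetration check between adjacent vertebrae:
  # shrunken core boxes around each centroid must stay disjoint
  cores <- lapply(out, function(m) {
    bb <- mesh_bbox(m)
    c0 <- colMeans(bb)
    half <- 0.45 * (bb[2L, ] - bb[1L, ]) / 2
    rbind(c0 - half, c0 + half)
  })
  for (i in seq_len(n - 1L)) {
    a <- cores[[i]]; b <- cores[[i + 1L]]
    if (all(a[1L, ] <= b[2L, ] & b[1L, ] <= a[2L, ]))
      stop(sprintf("interpenetration: vertebrae %s and %s overlap after reposing",
                   names(out)[i], names(out)[i + 1L]))
  }
  labeled_spine(out)
}
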