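#' Chamfer distance between two point clouds
#'
#' Symmetric mean nearest-neighbour distance,
#' `CD = mean_p min_q d(p,q) + mean_q min_p d(q,p)`, with `d` the squared
#' Euclidean distance by default, multiplied by a reporting scale. The
#' conventional report is on unit-normalized clouds with `scale = 1e4`
#' (the convention of the point-cloud completion literature); the clouds are
#' used exactly as given, so
#' the caller decides on normalization.
#'
#' @param P,Q point matrices (`n x 3`) or [point_cloud()] objects; non-empty.
#' @param scale reporting multiplier (default `1e4`).
#' @param squared use squared Euclidean distances (default `TRUE`).
#' @return a non-negative scalar.
#' @export
chamfer <- function(P, Q, scale = 1e4, squared = TRUE) {
  P <- as_points(P); Q <- as_points(Q)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop("chamfer requires non-empty clouds")
  d2_pq <- cpp_nn(P, Q)$d2
  d2_qp <- cpp_nn(Q, P)$d2
  if (!squared) {
    d2_pq <- sqrt(d2_pq)
    d2_qp <- sqrt(d2_qp)
  }
  (mean(d2_pq) + mean(d2_qp)) * scale
}

#' Earth Mover's Distance between equal-size point clouds
#'
#' Mean per-point transport cost under the optimal one-to-one assignment with
#' Euclidean ground cost. Solved exactly (shortest augmenting path) up to
#' `exact_max` points; above that an entropic (Sinkhorn) approximation is
#' used and the regularization epsilon is attached as attribute `"epsilon"`.
#'
#' @param P,Q point matrices or [point_cloud()]s with `|P| == |Q|`.
#' @param exact_max largest cardinality solved exactly (default 512).
#' @return scalar mean transport cost (attribute `"epsilon"` when approximate).
#' @export
emd <- function(P, Q, exact_max = 512L) {
  P <- as_points(P); Q <- as_points(Q)
  if (nrow(P) != nrow(Q))
    stop(sprintf("EMD requires equal cardinalities (got %d and %d)", nrow(P), nrow(Q)))
  if (nrow(P) == 0L) stop("EMD requires non-empty clouds")
  n <- nrow(P)
  cost <- sqrt(pmax(cross_dist2(P, Q), 0))
  if (n <= exact_max) {
    sol <- cpp_assignment(cost)
    sol$cost / n
  } else {
    eps <- 0.01 * stats::median(cost)
    res <- sinkhorn_cost(cost, eps)
    structure(res, epsilon = eps)
  }
}

#' F-score between two point clouds at a distance threshold
#'
#' Precision is the fraction of `P` within `d_threshold` of `Q`; recall the
#' fraction of `Q` within `d_threshold` of `P`; F1 their harmonic mean
#' (0 when both are 0). The default threshold is 1\% of the bounding-box
#' diagonal of `Q` (the reference cloud).
#'
#' @param P,Q point matrices or [point_cloud()]s; non-empty.
#' @param d_threshold distance threshold in the clouds' units; default
#'   `0.01 * diag(bbox(Q))`.
#' @return named vector `c(precision, recall, f1)`.
#' @export
fscore <- function(P, Q, d_threshold = NULL) {
  P <- as_points(P); Q <- as_points(Q)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop("fscore requires non-empty clouds")
  if (is.null(d_threshold)) {
    bb <- cloud_bbox(Q)
    d_threshold <- 0.01 * sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  }
  if (d_threshold <= 0) stop("d_threshold must be positive")
  prec <- mean(sqrt(cpp_nn(P, Q)$d2) < d_threshold)
  rec <- mean(sqrt(cpp_nn(Q, P)$d2) < d_threshold)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

#' Spinous-process centerline annotation
#'
#' An ordered polyline along the spinous-process crest, in mm.
#'
#' @param points ordered polyline vertices (`>= 2` rows, consecutive points
#'   distinct).
#' @param source `"input"` or `"completion"`.
#' @return object of class `centerline_annotation`.
#' @export
centerline_annotation <- function(points, source = c("input", "completion")) {
  points <- as_xyz(points, "points")
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points")
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0)) stop("consecutive centerline points must be distinct")
  structure(list(points = points, source = match.arg(source)),
            class = "centerline_annotation")
}

#' Chamfer distance between spinous-process centerlines
#'
#' Both polylines are densified to at most `spacing_mm` point spacing by
#' linear interpolation, then compared with [chamfer()] under the same
#' squared/scale convention as the main metric.
#'
#' @param pred,ref [centerline_annotation()]s.
#' @param scale,squared passed to [chamfer()].
#' @param spacing_mm densification spacing (default 0.5 mm).
#' @return scalar.
#' @export
sp_centerline_cd <- function(pred, ref, scale = 1e4, squared = TRUE,
                             spacing_mm = 0.5) {
  stopifnot(inherits(pred, "centerline_annotation"),
            inherits(ref, "centerline_annotation"))
  chamfer(densify_polyline(pred$points, spacing_mm),
          densify_polyline(ref$points, spacing_mm),
          scale = scale, squared = squared)
}

#' Facet-joint landmark
#'
#' @param level vertebra level tag (`"L1"` .. `"L5"`).
#' @param side `"left"` or `"right"`.
#' @param center 3D point in mm.
#' @return object of class `facet_landmark`.
#' @export
facet_landmark <- function(level, side = c("left", "right"), center) {
  side <- match.arg(side)
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must be a 3D point")
  structure(list(level = level, side = side, center = center),
            class = "facet_landmark")
}

#' Distance between matching facet-joint centers
#'
#' @param pred,gt [facet_landmark()]s with identical level and side.
#' @return Euclidean distance in mm.
#' @export
facet_distance <- function(pred, gt) {
  stopifnot(inherits(pred, "facet_landmark"), inherits(gt, "facet_landmark"))
  if (!identical(pred$level, gt$level) || !identical(pred$side, gt$side))
    stop(sprintf("landmark pairing mismatch: %s/%s vs %s/%s",
                 pred$level, pred$side, gt$level, gt$side))
  sqrt(sum((pred$center - gt$center)^2))
}

#' Aggregate a per-item metrics table
#'
#' Takes one row per evaluated vertebra (columns such as `cd_scaled`, `emd`,
#' `f1`, `precision`, `recall`, `sp_cd`, `facet_left_mm`, `facet_right_mm`;
#' missing values allowed) and appends per-column mean and median aggregates
#' over non-missing entries. When both facet columns are present, each
#' level's pair is flagged acceptable if the mean of its left and right
#' distances is at most `facet_tolerance_mm` (5 mm: the placement error still
#' compatible with a successful facet-joint injection).
#'
#' @param rows data frame of per-item metric rows.
#' @param facet_tolerance_mm acceptability threshold (default 5).
#' @return object of class `metrics_report`: list with `rows`, `aggregate`
#'   (mean/median data frame), `facet_acceptable` (logical per level with
#'   both facet values) and `n_acceptable`.
#' @export
summarize_metrics <- function(rows, facet_tolerance_mm = 5) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("summarize_metrics needs at least one row")
  num_cols <- names(rows)[vapply(rows, is.numeric, logical(1))]
  agg <- data.frame(statistic = c("mean", "median"))
  for (cn in num_cols) {
    v <- rows[[cn]]
    v <- v[is.finite(v)]
    agg[[cn]] <- if (length(v)) c(mean(v), stats::median(v)) else c(NA_real_, NA_real_)
  }
  facet_acceptable <- NULL
  n_acceptable <- NA_integer_
  if (all(c("facet_left_mm", "facet_right_mm") %in% names(rows))) {
    both <- is.finite(rows$facet_left_mm) & is.finite(rows$facet_right_mm)
    if (any(both)) {
      pair_mean <- (rows$facet_left_mm[both] + rows$facet_right_mm[both]) / 2
      facet_acceptable <- pair_mean <= facet_tolerance_mm
      names(facet_acceptable) <- if ("level" %in% names(rows))
        as.character(rows$level[both]) else as.character(which(both))
      n_acceptable <- sum(facet_acceptable)
    }
  }
  structure(list(rows = rows, aggregate = agg,
                 facet_acceptable = facet_acceptable,
                 n_acceptable = n_acceptable,
                 facet_tolerance_mm = facet_tolerance_mm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d items\n", nrow(x$rows)))
  print(x$aggregate, row.names = FALSE)
  if (!is.null(x$facet_acceptable))
    cat(sprintf("facet pairs within %.1f mm: %d of %d\n",
                x$facet_tolerance_mm, x$n_acceptable, length(x$facet_acceptable)))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

as_points <- function(x) {
  if (inherits(x, "point_cloud")) x$points else as_xyz(x, "points")
}

cross_dist2 <- function(P, Q) {
  pn <- rowSums(P^2)
  qn <- rowSums(Q^2)
  outer(pn, qn, `+`) - 2 * P %*% t(Q)
}

densify_polyline <- function(points, spacing) {
  out <- list(points[1L, , drop = FALSE])
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / spacing))
    t <- seq_len(nseg) / nseg
    out[[i + 1L]] <- outer(1 - t, a) + outer(t, b)
  }
  do.call(rbind, out)
}

sinkhorn_cost <- function(cost, eps, iters = 300L) {
  n <- nrow(cost)
  K <- exp(-cost / eps)
  u <- rep(1 / n, n); v <- rep(1 / n, n)
  r <- rep(1 / n, n)
  for (i in seq_len(iters)) {
    u <- r / pmax(K %*% v, 1e-300)
    v <- r / pmax(t(K) %*% u, 1e-300)
  }
  plan <- diag(as.vector(u)) %*% K %*% diag(as.vector(v))
  # plan marginals are 1/n each (total mass 1), so the expected cost under the
  # coupling is already the mean per-point transport cost
  sum(plan * cost) / sum(plan)
}
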