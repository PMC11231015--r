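# Independent brute-force oracles and tiny geometric fixtures used across the
# suite. Everything here is deliberately naive (double loops, exhaustive
# enumeration) and shares no code path with the package internals it checks.

# Exhaustive double-loop Chamfer distance.
chamfer_oracle <- function(P, Q, scale = 1e4, squared = TRUE) {
  d_pq <- vapply(seq_len(nrow(P)), function(i)
    min(colSums((t(Q) - P[i, ])^2)), numeric(1))
  d_qp <- vapply(seq_len(nrow(Q)), function(j)
    min(colSums((t(P) - Q[j, ])^2)), numeric(1))
  if (!squared) { d_pq <- sqrt(d_pq); d_qp <- sqrt(d_qp) }
  (mean(d_pq) + mean(d_qp)) * scale
}

# Exact minimum-cost assignment by dynamic programming over column subsets
# (O(n^2 2^n)); equivalent to enumerating all n! permutations.
assignment_oracle <- function(cost) {
  n <- nrow(cost)
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(Inf, full + 1L)
  best[1L] <- 0
  for (mask in 0:(full - 1L)) {
    if (!is.finite(best[mask + 1L])) next
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L) + 1L  # next row
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      v <- best[mask + 1L] + cost[i, j]
      if (v < best[bitwOr(mask, bit) + 1L]) best[bitwOr(mask, bit) + 1L] <- v
    }
  }
  best[full + 1L]
}

emd_oracle <- function(P, Q) {
  cost <- as.matrix(stats::dist(rbind(P, Q)))[seq_len(nrow(P)),
                                              nrow(P) + seq_len(nrow(Q))]
  assignment_oracle(cost) / nrow(P)
}

# Scalar Moller-Trumbore for the ray-casting oracle.
ray_tri_oracle <- function(o, d, a, b, cc) {
  e1 <- b - a; e2 <- cc - a
  p <- c(d[2] * e2[3] - d[3] * e2[2], d[3] * e2[1] - d[1] * e2[3],
         d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * p)
  if (abs(det) < 1e-14) return(NA_real_)
  s <- o - a
  u <- sum(s * p) / det
  if (u < -1e-12 || u > 1 + 1e-12) return(NA_real_)
  q <- c(s[2] * e1[3] - s[3] * e1[2], s[3] * e1[1] - s[1] * e1[3],
         s[1] * e1[2] - s[2] * e1[1])
  v <- sum(d * q) / det
  if (v < -1e-12 || u + v > 1 + 1e-12) return(NA_real_)
  t <- sum(e2 * q) / det
  if (t <= 1e-8) return(NA_real_)
  t
}

# Exhaustive all-faces first-hit ray casting with incidence filtering:
# the independent reference for raycast_visible.
raycast_oracle <- function(meshes, camera, dirs, max_incidence_deg = 90) {
  if (inherits(meshes, "triangle_mesh")) meshes <- list(L1 = meshes)
  rows <- list()
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    best_t <- Inf; best <- NULL
    for (mi in seq_along(meshes)) {
      m <- meshes[[mi]]
      for (f in seq_len(nrow(m$faces))) {
        tri <- m$vertices[m$faces[f, ], , drop = FALSE]
        t <- ray_tri_oracle(camera$position, d, tri[1, ], tri[2, ], tri[3, ])
        if (!is.na(t) && t < best_t) {
          n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
          n <- n / sqrt(sum(n^2))
          best_t <- t
          best <- list(t = t, level = names(meshes)[mi], normal = n)
        }
      }
    }
    if (is.null(best)) next
    inc <- acos(min(1, max(-1, -sum(d * best$normal)))) * 180 / pi
    if (inc >= max_incidence_deg) next
    rows[[length(rows) + 1L]] <- data.frame(
      ray = r, t = best$t, level = best$level, incidence = inc)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Axis-aligned box mesh with outward-oriented faces.
box_mesh <- function(center = c(0, 0, 0), size = c(1, 1, 1)) {
  h <- size / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  triangle_mesh(v, f)
}

# Rectangular plane (two triangles) with normal along +nrm_axis.
plane_mesh <- function(center, u, v, half_u, half_v) {
  p <- rbind(center - half_u * u - half_v * v, center + half_u * u - half_v * v,
             center + half_u * u + half_v * v, center - half_u * u + half_v * v)
  triangle_mesh(p, rbind(c(1, 2, 3), c(1, 3, 4)))
}

# Coarse UV sphere mesh (<= 200 faces for oracle scenes).
sphere_mesh <- function(radius = 1, center = c(0, 0, 0), n_lat = 8L, n_lon = 12L) {
  th <- seq(0, pi, length.out = n_lat + 1L)
  ph <- seq(0, 2 * pi, length.out = n_lon + 1L)[-1L]
  verts <- rbind(c(0, 0, radius), c(0, 0, -radius))
  idx <- function(i, j) 2L + (i - 1L) * n_lon + j   # rings 1..n_lat-1
  for (i in seq_len(n_lat - 1L)) for (j in seq_len(n_lon))
    verts <- rbind(verts, radius * c(sin(th[i + 1]) * cos(ph[j]),
                                     sin(th[i + 1]) * sin(ph[j]),
                                     cos(th[i + 1])))
  faces <- list()
  for (j in seq_len(n_lon)) {
    jn <- j %% n_lon + 1L
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, jn))
    faces[[length(faces) + 1L]] <- c(2L, idx(n_lat - 1L, jn), idx(n_lat - 1L, j))
  }
  for (i in seq_len(n_lat - 2L)) for (j in seq_len(n_lon)) {
    jn <- j %% n_lon + 1L
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, jn), idx(i, jn))
  }
  triangle_mesh(sweep(verts, 2, center, "+"), do.call(rbind, faces))
}

# Connected-components check via union-find over mesh edges.
mesh_is_connected <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    for (e in list(f[1:2], f[2:3], f[c(1, 3)])) {
      a <- find(e[1]); b <- find(e[2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

# Tiny deterministic spine used by several files (cached per session).
small_spine <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_spine(n_levels = 3L, seed = 17L)
    cache
  }
})
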