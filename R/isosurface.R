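# Voxel-boundary (cuberille) iso-surface extraction of a binary mask at the
# 0.5 level: every exposed voxel face becomes a quad (two triangles) with
# outward orientation. Vertices lie on half-integer voxel-corner coordinates
# and are welded, so the surface is closed wherever the mask is.
cuberille_mesh <- function(mask, affine = diag(4)) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3D array")
  if (!any(mask)) stop("mask is empty: no surface to extract")
  quad_corners <- list()   # each entry: 4k x 3 doubled-integer corner coords, quad-major
  quad_signs <- list()
  for (a in 1:3) {
    for (s in c(1L, -1L)) {
      # neighbor mask along +/- axis a (FALSE outside the array)
      n_a <- d[a]
      nb <- array(FALSE, d)
      if (n_a > 1L) {
        src <- lapply(d, seq_len); dst <- lapply(d, seq_len)
        if (s == 1L) { dst[[a]] <- seq_len(n_a - 1L); src[[a]] <- 2:n_a }
        else         { dst[[a]] <- 2:n_a;             src[[a]] <- seq_len(n_a - 1L) }
        nb <- do.call(`[<-`, c(list(nb), dst, list(do.call(`[`, c(list(mask), src)))))
      }
      boundary <- mask & !nb
      if (!any(boundary)) next
      vox <- which(boundary, arr.ind = TRUE) - 1L   # 0-based voxel centers
      k <- nrow(vox)
      b <- (a %% 3L) + 1L; cc <- (b %% 3L) + 1L     # cyclic: e_b x e_c = e_a
      center2 <- 2L * vox
      center2[, a] <- center2[, a] + s
      corner <- function(sb, sc) {
        m <- center2
        m[, b] <- m[, b] + sb
        m[, cc] <- m[, cc] + sc
        m
      }
      c1 <- corner(-1L, -1L); c2 <- corner(1L, -1L)
      c3 <- corner(1L, 1L);   c4 <- corner(-1L, 1L)
      # quad-major layout: rows 4i-3..4i are the corners of quad i
      block <- matrix(0L, 4L * k, 3L)
      block[seq_len(k) * 4L - 3L, ] <- c1
      block[seq_len(k) * 4L - 2L, ] <- c2
      block[seq_len(k) * 4L - 1L, ] <- c3
      block[seq_len(k) * 4L, ] <- c4
      quad_corners[[length(quad_corners) + 1L]] <- block
      quad_signs[[length(quad_signs) + 1L]] <- rep(s, k)
    }
  }
  corners2 <- do.call(rbind, quad_corners)
  sgn <- unlist(quad_signs)
  nq <- length(sgn)
  key <- paste(corners2[, 1L], corners2[, 2L], corners2[, 3L])
  uq <- !duplicated(key)
  vid <- match(key, key[uq])
  verts_vox <- corners2[uq, , drop = FALSE] / 2
  base <- (seq_len(nq) - 1L) * 4L
  r1 <- vid[base + 1L]; r2 <- vid[base + 2L]; r3 <- vid[base + 3L]; r4 <- vid[base + 4L]
  fwd <- sgn == 1L
  faces <- matrix(0L, 2L * nq, 3L)
  # corners ordered so (c2-c1) x (c4-c1) = +e_a; reverse winding for -e_a faces
  faces[seq_len(nq) * 2L - 1L, ] <- cbind(r1, ifelse(fwd, r2, r3), ifelse(fwd, r3, r2))
  faces[seq_len(nq) * 2L, ] <- cbind(r1, ifelse(fwd, r3, r4), ifelse(fwd, r4, r3))
  A <- affine
  world <- verts_vox %*% t(A[1:3, 1:3]) +
    matrix(A[1:3, 4L], nrow(verts_vox), 3L, byrow = TRUE)
  if (det(A[1:3, 1:3]) < 0) faces <- faces[, c(1L, 3L, 2L)]
  triangle_mesh(world, faces)
}

# Uniform Laplacian smoothing (lambda-damped umbrella operator).
laplacian_smooth <- function(mesh, iterations = 1L, lambda = 0.5) {
  v <- mesh$vertices
  f <- mesh$faces
  e_from <- c(f[, 1L], f[, 2L], f[, 3L], f[, 2L], f[, 3L], f[, 1L])
  e_to <- c(f[, 2L], f[, 3L], f[, 1L], f[, 1L], f[, 2L], f[, 3L])
  for (it in seq_len(iterations)) {
    s <- rowsum(v[e_to, , drop = FALSE], e_from)
    cnt <- rowsum(rep(1, length(e_from)), e_from)
    target <- s / as.vector(cnt)
    idx <- as.integer(rownames(s))
    v[idx, ] <- (1 - lambda) * v[idx, , drop = FALSE] + lambda * target
  }
  triangle_mesh(v, f, NULL)
}

# Trilinear interpolation of a 3D scalar grid at continuous voxel coordinates
# (0-based; grid point g[i+1,j+1,k+1] sits at coordinate (i,j,k)).
trilinear <- function(grid, coords) {
  d <- dim(grid)
  x <- pmin(pmax(coords[, 1L], 0), d[1L] - 1 - 1e-9)
  y <- pmin(pmax(coords[, 2L], 0), d[2L] - 1 - 1e-9)
  z <- pmin(pmax(coords[, 3L], 0), d[3L] - 1 - 1e-9)
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  at <- function(di, dj, dk)
    grid[cbind(i0 + di + 1L, j0 + dj + 1L, k0 + dk + 1L)]
  v000 <- at(0, 0, 0); v100 <- at(1, 0, 0); v010 <- at(0, 1, 0); v110 <- at(1, 1, 0)
  v001 <- at(0, 0, 1); v101 <- at(1, 0, 1); v011 <- at(0, 1, 1); v111 <- at(1, 1, 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}
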