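#' Camera pose for ultrasound-view simulation
#'
#' @param position camera position (mm).
#' @param view_dir unit viewing direction (the beam axis).
#' @param up unit up vector, orthogonal to `view_dir` (the sweep/elevation
#'   direction of the fan).
#' @return object of class `camera_pose`.
#' @export
camera_pose <- function(position, view_dir, up) {
  position <- as.numeric(position); view_dir <- as.numeric(view_dir); up <- as.numeric(up)
  if (abs(sqrt(sum(view_dir^2)) - 1) > 1e-6 || abs(sqrt(sum(up^2)) - 1) > 1e-6)
    stop("view_dir and up must be unit vectors (within 1e-6)")
  if (abs(sum(view_dir * up)) > 1e-6)
    stop("view_dir and up must be orthogonal (within 1e-6)")
  structure(list(position = position, view_dir = view_dir, up = up),
            class = "camera_pose")
}

#' Place virtual cameras over the spinous processes
#'
#' Mimics a transverse ultrasound sweep: one camera is placed `height_mm`
#' posterior to each level's spinous-process apex (the most posterior vertex
#' of that level's mesh), viewing anteriorly, and additional poses are
#' interpolated along the sweep path at `sweep_step_mm` spacing.
#'
#' @param spine a [labeled_spine()].
#' @param height_mm stand-off distance from apex to camera (> 0).
#' @param sweep_step_mm spacing of interpolated sweep poses.
#' @param posterior_dir unit direction pointing posteriorly (out of the
#'   back); default `c(0, 1, 0)`, the fixture convention.
#' @return list of [camera_pose()]s.
#' @export
place_cameras <- function(spine, height_mm = 120, sweep_step_mm = 15,
                          posterior_dir = c(0, 1, 0)) {
  stopifnot(inherits(spine, "labeled_spine"))
  if (height_mm <= 0) stop("height_mm must be positive")
  posterior_dir <- unit(posterior_dir)
  apexes <- t(vapply(spine$levels, function(m) {
    proj <- drop(m$vertices %*% posterior_dir)
    if (diff(range(proj)) < 1e-9)
      stop("degenerate mesh: no posterior extremum to anchor the camera")
    m$vertices[which.max(proj), ]
  }, numeric(3)))
  anchors <- sweep(apexes, 2L, height_mm * posterior_dir, "+")
  # sweep path: polyline through the per-level anchors, resampled
  pos <- anchors[1L, , drop = FALSE]
  if (nrow(anchors) > 1L) {
    for (i in seq_len(nrow(anchors) - 1L)) {
      a <- anchors[i, ]; b <- anchors[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      nseg <- max(1L, ceiling(len / sweep_step_mm))
      t <- seq_len(nseg) / nseg
      pos <- rbind(pos, outer(1 - t, a) + outer(t, b))
    }
  }
  view <- -posterior_dir
  lapply(seq_len(nrow(pos)), function(i) {
    # up along the local sweep tangent, orthogonalized against the view axis
    tangent <- if (nrow(pos) == 1L) c(0, 0, 1) else if (i < nrow(pos))
      pos[i + 1L, ] - pos[i, ] else pos[i, ] - pos[i - 1L, ]
    tangent <- tangent - sum(tangent * view) * view
    if (sqrt(sum(tangent^2)) < 1e-9) tangent <- c(0, 0, 1) - sum(c(0, 0, 1) * view) * view
    camera_pose(pos[i, ], view, unit(tangent))
  })
}

ray_fan <- function(camera, grid) {
  n_u <- grid[[1L]]; n_v <- grid[[2L]]; width <- grid[[3L]] * pi / 180
  if (n_u < 1L || n_v < 1L) stop("grid dimensions must be at least 1")
  rgt <- unit(cross3(camera$view_dir, camera$up))
  au <- if (n_u == 1L) 0 else seq(-width / 2, width / 2, length.out = n_u)
  av <- if (n_v == 1L) 0 else seq(-width / 2, width / 2, length.out = n_v)
  ang <- as.matrix(expand.grid(u = au, v = av))
  dirs <- matrix(rep(camera$view_dir, each = nrow(ang)), ncol = 3L) +
    outer(tan(ang[, 1L]), rgt) + outer(tan(ang[, 2L]), camera$up)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(dirs = dirs, right = rgt)
}

scene_from <- function(meshes) {
  if (inherits(meshes, "labeled_spine")) meshes <- meshes$levels
  if (inherits(meshes, "triangle_mesh")) meshes <- list(L1 = meshes)
  if (is.null(names(meshes))) names(meshes) <- paste0("L", seq_along(meshes))
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  F <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$faces + off[i] - 1L))  # 0-based for C++
  mesh_id <- rep(seq_along(meshes), vapply(meshes, function(m) nrow(m$faces), integer(1)))
  list(V = V, F = F, mesh_id = mesh_id, levels = names(meshes))
}

cast_scene <- function(scene, camera, dirs, right) {
  cpp_first_hit(camera$position, dirs, scene$V, scene$F, scene$mesh_id,
                right, camera$up, camera$view_dir)
}

hits_frame <- function(res, dirs, scene, max_incidence_deg, keep = NULL) {
  sel <- which(res$hit)
  if (!is.null(keep)) sel <- intersect(sel, keep)
  if (length(sel) == 0L) return(empty_hits())
  d <- dirs[sel, , drop = FALSE]
  n <- cbind(res$nx[sel], res$ny[sel], res$nz[sel])
  # incidence: angle between the ray direction and the inward surface normal
  # (outward face normal flipped); 0 = normal incidence, 90 = grazing
  cosang <- pmin(1, pmax(-1, -rowSums(d * n)))
  inc <- acos(cosang) * 180 / pi
  df <- data.frame(x = res$px[sel], y = res$py[sel], z = res$pz[sel],
                   nx = n[, 1L], ny = n[, 2L], nz = n[, 3L],
                   incidence_deg = inc,
                   source_level = scene$levels[res$mesh[sel]],
                   ray = sel, t = res$t[sel], stringsAsFactors = FALSE)
  df[df$incidence_deg < max_incidence_deg, , drop = FALSE]
}

empty_hits <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             nx = numeric(0), ny = numeric(0), nz = numeric(0),
             incidence_deg = numeric(0), source_level = character(0),
             ray = integer(0), t = numeric(0), stringsAsFactors = FALSE)
}

#' Incidence-angle-aware first-hit ray casting
#'
#' Casts an `n_u x n_v` fan of rays of the given angular width about the
#' camera's viewing direction against all meshes and keeps, per ray, only the
#' first intersection (acoustic shadowing: nothing behind the first bone
#' interface is visible). Hits whose incidence angle -- between the ray
#' direction and the inward surface normal -- reaches `max_incidence_deg`
#' are discarded (grazing interfaces return no echo).
#'
#' @param meshes a [labeled_spine()], a named list of [triangle_mesh()]es,
#'   or a single mesh.
#' @param camera a [camera_pose()].
#' @param grid `c(n_u, n_v, fan_width_deg)`.
#' @param max_incidence_deg angular visibility cut in (0, 180], default 90.
#' @return data frame of ray hits: point (`x,y,z`), outward face normal
#'   (`nx,ny,nz`), `incidence_deg`, `source_level`, ray index and depth `t`.
#' @export
raycast_visible <- function(meshes, camera, grid = c(64, 64, 60),
                            max_incidence_deg = 90) {
  stopifnot(inherits(camera, "camera_pose"))
  if (max_incidence_deg <= 0 || max_incidence_deg > 180)
    stop("max_incidence_deg must be in (0, 180]")
  scene <- scene_from(meshes)
  fan <- ray_fan(camera, grid)
  res <- cast_scene(scene, camera, fan$dirs, fan$right)
  hits_frame(res, fan$dirs, scene, max_incidence_deg)
}

#' Ray casting with ultrasound scattering emulation
#'
#' Emulates off-plane scattering echoes: a copy of every mesh is translated
#' by `+shift_mm` and `-shift_mm` along the transverse (left-right) direction
#' perpendicular to the beam, and the shifted copies act as additional
#' occluders. A hit on an original mesh is retained only if no shifted copy
#' intersects that ray strictly closer to the camera; hits on copies are
#' never emitted, so the result is a subset of [raycast_visible()].
#'
#' @inheritParams raycast_visible
#' @param shift_mm non-negative transverse shift magnitude (0 = identity).
#' @return data frame as in [raycast_visible()].
#' @export
apply_scatter <- function(meshes, camera, shift_mm = 2, grid = c(64, 64, 60),
                          max_incidence_deg = 90) {
  if (shift_mm < 0) stop("shift_mm must be non-negative")
  if (shift_mm == 0) return(raycast_visible(meshes, camera, grid, max_incidence_deg))
  scene <- scene_from(meshes)
  fan <- ray_fan(camera, grid)
  res_orig <- cast_scene(scene, camera, fan$dirs, fan$right)
  shift <- shift_mm * fan$right
  shifted <- scene
  shifted$V <- rbind(sweep(scene$V, 2L, shift, "+"), sweep(scene$V, 2L, shift, "-"))
  shifted$F <- rbind(scene$F, scene$F + nrow(scene$V))
  shifted$mesh_id <- rep(1L, nrow(shifted$F))
  shifted$levels <- "shifted"
  res_sh <- cast_scene(shifted, camera, fan$dirs, fan$right)
  blocked <- res_sh$hit & res_sh$t < res_orig$t - 1e-9
  keep <- which(res_orig$hit & !blocked)
  hits_frame(res_orig, fan$dirs, scene, max_incidence_deg, keep = keep)
}

#' Mask ray hits into a single-vertebra partial view
#'
#' @param hits data frame from [raycast_visible()] or [apply_scatter()].
#' @param level level tag to extract.
#' @param cameras optional list of the contributing [camera_pose()]s
#'   (provenance).
#' @param scatter_applied,shift_mm provenance flags.
#' @return object of class `partial_view` holding the level's labeled
#'   [point_cloud()] and acquisition provenance.
#' @export
mask_by_vertebra <- function(hits, level, cameras = list(),
                             scatter_applied = FALSE, shift_mm = 0) {
  sel <- hits$source_level == level
  if (!any(sel))
    stop(sprintf("empty view: no visible points for level %s", level))
  h <- hits[sel, , drop = FALSE]
  cloud <- point_cloud(cbind(h$x, h$y, h$z), cbind(h$nx, h$ny, h$nz),
                       labels = h$source_level)
  structure(list(cloud = cloud, level = level, cameras = cameras,
                 scatter_applied = scatter_applied,
                 fusion_applied = FALSE, shift_mm = shift_mm),
            class = "partial_view")
}

#' @export
print.partial_view <- function(x, ...) {
  cat(sprintf("partial_view %s: %d points (scatter %s, fusion %s)\n",
              x$level, nrow(x$cloud$points),
              if (x$scatter_applied) "on" else "off",
              if (x$fusion_applied) "on" else "off"))
  invisible(x)
}

#' Neighboring cloud fusion
#'
#' Emulates imperfect vertebra-level separation in ultrasound: each view
#' gains `round(fraction * n_neighbor)` points from each directly adjacent
#' view, drawn (seeded) preferentially from the band of the neighbor nearest
#' the shared boundary (by default the quarter of the neighbor's
#' cranio-caudal extent closest to the boundary). Fused points keep their
#' original level labels so ground-truth pairing stays clean.
#'
#' @param views list of [mask_by_vertebra()] views ordered by level.
#' @param fraction fraction of each neighbor's points to fuse, in `[0, 1]`.
#' @param seed integer seed.
#' @param band_fraction extent fraction of the eligible boundary band.
#' @return list of fused `partial_view`s.
#' @export
fuse_neighbors <- function(views, fraction = 0.15, seed = 1L,
                           band_fraction = 0.25) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (fraction == 0) return(views)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  centroids <- t(vapply(views, function(v) colMeans(v$cloud$points), numeric(3)))
  out <- views
  for (i in seq_along(views)) {
    add_pts <- list(); add_nrm <- list(); add_lab <- list()
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > length(views)) next
      nb <- views[[j]]$cloud
      n_j <- nrow(nb$points)
      count <- min(round(fraction * n_j), n_j)
      if (count == 0L) next
      axis <- centroids[i, ] - centroids[j, ]
      len <- sqrt(sum(axis^2))
      axis <- if (len < 1e-9) c(0, 0, 1) else axis / len
      proj <- drop(nb$points %*% axis)   # larger = closer to view i
      ord <- order(proj, decreasing = TRUE)
      band_n <- max(count, ceiling(band_fraction * n_j))
      pool <- ord[seq_len(min(band_n, n_j))]
      set.seed((as.numeric(seed) * 131071 + i * 8191 + j * 127) %% 2147483629)
      take <- if (count >= length(pool)) pool else sample(pool, count)
      add_pts[[length(add_pts) + 1L]] <- nb$points[take, , drop = FALSE]
      add_nrm[[length(add_nrm) + 1L]] <- if (is.null(nb$normals)) NULL else nb$normals[take, , drop = FALSE]
      add_lab[[length(add_lab) + 1L]] <- if (is.null(nb$labels))
        rep(views[[j]]$level, length(take)) else nb$labels[take]
    }
    if (length(add_pts)) {
      base <- views[[i]]$cloud
      pts <- rbind(base$points, do.call(rbind, add_pts))
      nrm <- if (is.null(base$normals)) NULL else rbind(base$normals, do.call(rbind, add_nrm))
      lab <- c(base$labels %||% rep(views[[i]]$level, nrow(base$points)),
               unlist(add_lab))
      out[[i]]$cloud <- point_cloud(pts, nrm, lab)
    }
    out[[i]]$fusion_applied <- TRUE
  }
  out
}

#' Resample a point matrix to an exact cardinality
#'
#' Farthest-point subsampling when too many points; deterministic
#' duplicate-padding when too few.
#'
#' @param points `n x 3` matrix.
#' @param n target cardinality.
#' @return `n x 3` matrix.
#' @export
resample_points <- function(points, n) {
  m <- nrow(points)
  if (m == 0L) stop("cannot resample an empty point set")
  if (m == n) return(points)
  if (m > n) return(points[cpp_fps(points, n, 1L), , drop = FALSE])
  points[c(seq_len(m), rep_len(seq_len(m), n - m)), , drop = FALSE]
}

#' Default configuration for synthetic dataset generation
#'
#' @param n_curvatures curvature samples per spine.
#' @param posture `"sitting"` or `"prone"` (curvature bias).
#' @param joint_limit_deg physiological per-joint rotation limit.
#' @param height_mm,sweep_step_mm camera placement (see [place_cameras()]).
#' @param grid ray fan `c(n_u, n_v, fan_width_deg)`.
#' @param max_incidence_deg incidence visibility cut.
#' @param shift_mm scattering shift; 0 disables the scattering step.
#' @param fusion_fraction neighboring-cloud fusion fraction; 0 disables.
#' @param n_in,n_gt partial and ground-truth cloud cardinalities.
#' @return named list.
#' @export
dataset_config <- function(n_curvatures = 1L, posture = "sitting",
                           joint_limit_deg = 10, height_mm = 120,
                           sweep_step_mm = 15, grid = c(64, 64, 60),
                           max_incidence_deg = 90, shift_mm = 2,
                           fusion_fraction = 0.15, n_in = 2048L, n_gt = 2048L) {
  as.list(environment())
}

#' Generate ultrasound-consistent training pairs from spines
#'
#' For every spine and sampled curvature: repose the spine, place a camera
#' sweep over the spinous processes, ray-cast with acoustic shadowing,
#' incidence filtering and (optionally) scattering, mask the hits into
#' per-vertebra views, fuse neighboring clouds, and pair each partial view
#' with `n_gt` points uniformly area-sampled from that vertebra's complete
#' mesh surface. Both clouds are normalized with the ground-truth cloud's
#' unit-sphere transform. A failing stage excludes that sample (recorded in
#' the manifest); the run fails only if no pairs result.
#'
#' @param spines list of [labeled_spine()]s (or a single one).
#' @param config list from [dataset_config()].
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, paired PLY files and a
#'   JSON-lines manifest are written.
#' @return list with `pairs` (list of `training_pair`s) and `manifest`
#'   (data frame).
#' @export
generate_dataset <- function(spines, config = dataset_config(), seed = 1L,
                             out_dir = NULL) {
  if (inherits(spines, "labeled_spine")) spines <- list(spines)
  if (length(spines) < 1L) stop("need at least one spine")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  pairs <- list()
  manifest <- list()
  for (si in seq_along(spines)) {
    spine <- spines[[si]]
    n_joints <- length(spine$levels) - 1L
    for (ci in seq_len(config$n_curvatures)) {
      sub_seed <- (as.numeric(seed) * 48611 + si * 7919 + ci * 104729) %% 2147483629
      status <- "ok"
      deformed <- spine
      curv <- NULL
      if (n_joints >= 1L) {
        curv <- sample_curvature(config$posture, config$joint_limit_deg,
                                 n_joints, seed = sub_seed)
        deformed <- tryCatch(deform_spine(spine, curv), error = function(e) {
          status <<- conditionMessage(e); NULL
        })
        if (is.null(deformed)) {
          manifest[[length(manifest) + 1L]] <- data.frame(
            spine = si, curvature = ci, level = NA, status = status,
            seed = sub_seed)
          next
        }
      }
      cams <- place_cameras(deformed, config$height_mm, config$sweep_step_mm)
      hit_list <- lapply(cams, function(cam) {
        if (config$shift_mm > 0)
          apply_scatter(deformed, cam, config$shift_mm, config$grid,
                        config$max_incidence_deg)
        else raycast_visible(deformed, cam, config$grid, config$max_incidence_deg)
      })
      hits <- do.call(rbind, hit_list)
      views <- list()
      for (lev in names(deformed$levels)) {
        v <- tryCatch(mask_by_vertebra(hits, lev, cams,
                                       scatter_applied = config$shift_mm > 0,
                                       shift_mm = config$shift_mm),
                      error = function(e) NULL)
        if (!is.null(v)) views[[lev]] <- v
      }
      if (config$fusion_fraction > 0 && length(views) > 1L)
        views <- fuse_neighbors(views, config$fusion_fraction, seed = sub_seed)
      for (lev in names(views)) {
        view <- views[[lev]]
        set.seed((sub_seed + match(lev, names(deformed$levels)) * 15485863) %% 2147483629)
        gt_pts <- sample_mesh_surface(deformed$levels[[lev]], config$n_gt)
        gt_norm <- normalize_cloud(point_cloud(gt_pts))
        partial_pts <- resample_points(view$cloud$points, config$n_in)
        pair <- structure(list(
          partial = point_cloud(apply_norm_transform(partial_pts, gt_norm$transform)),
          complete = gt_norm$cloud,
          transform = gt_norm$transform,
          level = lev, spine_id = si, curvature_id = ci),
          class = "training_pair")
        pairs[[length(pairs) + 1L]] <- pair
        manifest[[length(manifest) + 1L]] <- data.frame(
          spine = si, curvature = ci, level = lev, status = "ok",
          seed = sub_seed, n_partial_raw = nrow(view$cloud$points),
          n_in = config$n_in, n_gt = config$n_gt,
          scatter = config$shift_mm > 0, fusion = config$fusion_fraction > 0)
      }
    }
  }
  if (length(pairs) == 0L) stop("dataset generation produced zero pairs")
  manifest <- do.call(rbind, lapply(manifest, function(m) {
    miss <- setdiff(c("spine", "curvature", "level", "status", "seed",
                      "n_partial_raw", "n_in", "n_gt", "scatter", "fusion"),
                    names(m))
    for (nm in miss) m[[nm]] <- NA
    m
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      base <- sprintf("pair_%04d_s%d_c%d_%s", k, p$spine_id, p$curvature_id, p$level)
      write_pointcloud(p$partial, file.path(out_dir, paste0(base, "_partial.ply")))
      write_pointcloud(p$complete, file.path(out_dir, paste0(base, "_complete.ply")))
    }
    con <- file(file.path(out_dir, "manifest.jsonl"), "w")
    for (r in seq_len(nrow(manifest)))
      writeLines(jsonlite::toJSON(c(as.list(manifest[r, ]),
                                    list(master_seed = seed, config = config)),
                                  auto_unbox = TRUE, digits = NA), con)
    close(con)
  }
  list(pairs = pairs, manifest = manifest)
}
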