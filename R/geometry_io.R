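#' Read a triangle mesh from PLY, OBJ or STL
#'
#' PLY is supported in its ASCII and binary little-endian dialects; STL in
#' ASCII and binary. The format is inferred from the file extension unless
#' given explicitly. Coordinates are interpreted as world millimetres.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"stl"`; default inferred.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         ply = {
           p <- read_ply(path)
           if (is.null(p$faces)) stop(sprintf("%s: PLY has no face element", path))
           triangle_mesh(p$vertices, p$faces, p$normals)
         },
         obj = read_obj(path),
         stl = read_stl(path),
         stop(sprintf("unsupported mesh format: %s", format)))
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"stl"`; default inferred from `path`.
#' @param binary write binary little-endian PLY instead of ASCII (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         ply = write_ply(path, mesh$vertices, faces = mesh$faces,
                         normals = mesh$normals, binary = binary),
         obj = write_obj(path, mesh),
         stl = write_stl_ascii(path, mesh),
         stop(sprintf("unsupported mesh format: %s", format)))
  invisible(path)
}

#' Write a point cloud to PLY or XYZ
#'
#' PLY is the canonical interchange format: it persists per-point normals and
#' vertebra level labels (as an integer `label` property). XYZ stores only
#' coordinates (plus normals when present) and drops labels.
#'
#' @param pc a [point_cloud()]; must be non-empty.
#' @param path output path.
#' @param format `"ply"` or `"xyz"`; default inferred from `path`.
#' @param binary write binary little-endian PLY.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(pc, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(pc, "point_cloud"))
  if (nrow(pc$points) == 0L) stop("cannot write an empty point cloud")
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         ply = write_ply(path, pc$points, normals = pc$normals,
                         labels = pc$labels, binary = binary),
         xyz = {
           m <- if (is.null(pc$normals)) pc$points else cbind(pc$points, pc$normals)
           write.table(format(m, digits = 17, scientific = FALSE, trim = TRUE),
                       path, row.names = FALSE, col.names = FALSE, quote = FALSE)
         },
         stop(sprintf("unsupported point-cloud format: %s", format)))
  invisible(path)
}

#' Read a point cloud from PLY or XYZ
#'
#' @param path file path.
#' @param format `"ply"` or `"xyz"`; default inferred.
#' @return a [point_cloud()].
#' @export
read_pointcloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         ply = {
           p <- read_ply(path)
           point_cloud(p$vertices, p$normals, p$labels)
         },
         xyz = {
           m <- as.matrix(read.table(path))
           if (ncol(m) >= 6L) point_cloud(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
           else point_cloud(m[, 1:3, drop = FALSE])
         },
         stop(sprintf("unsupported point-cloud format: %s", format)))
}

#' Extract per-vertebra meshes from a NIfTI label volume
#'
#' Each requested integer label is binarized and iso-surfaced at 0.5 on the
#' voxel mask (boundary-face extraction, no smoothing by default), then
#' transformed to world millimetres by the NIfTI affine. Levels are returned
#' ordered cranio-caudally by body centroid.
#'
#' @param volume path to a `.nii`/`.nii.gz` integer labelmap.
#' @param label_map named integer vector mapping level tags to voxel labels,
#'   e.g. `c(L1 = 20, L2 = 21, ...)`.
#' @param smooth number of Laplacian smoothing iterations (default 0).
#' @return a [labeled_spine()].
#' @export
labelvolume_to_spine <- function(volume, label_map, smooth = 0L) {
  if (!file.exists(volume)) stop(sprintf("file not found: %s", volume))
  img <- RNifti::readNifti(volume)
  affine <- structure(RNifti::xform(img), class = NULL)
  arr <- as.array(img)
  found <- sort(unique(as.vector(arr)))
  meshes <- list()
  for (lev in names(label_map)) {
    lab <- label_map[[lev]]
    mask <- arr == lab
    if (!any(mask))
      stop(sprintf("label %d (%s) absent from volume; labels found: %s",
                   lab, lev, paste(found, collapse = ", ")))
    mesh <- cuberille_mesh(mask, affine)
    if (smooth > 0L) mesh <- laplacian_smooth(mesh, iterations = smooth)
    meshes[[lev]] <- mesh
  }
  # order cranio-caudally by centroid along the dominant spread axis
  if (length(meshes) >= 2L) {
    cents <- t(vapply(meshes, mesh_centroid, numeric(3)))
    axis <- prcomp(cents, center = TRUE)$rotation[, 1L]
    proj <- drop(cents %*% axis)
    lev_num <- suppressWarnings(as.integer(sub("^L", "", names(meshes))))
    # orient the axis so the ordering starts at the lowest level number
    if (!any(is.na(lev_num)) && stats::cor(proj, lev_num) < 0) proj <- -proj
    meshes <- meshes[order(proj)]
  }
  labeled_spine(meshes)
}

#' Normalize a point cloud to the unit sphere
#'
#' Centers the cloud at its centroid and scales so the farthest point has
#' unit norm. The returned transform allows exact inversion.
#'
#' @param pc a [point_cloud()]; must be non-empty and non-degenerate.
#' @return list with `cloud` (normalized [point_cloud()]) and `transform`
#'   (list with `center` and `scale`).
#' @export
normalize_cloud <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  if (nrow(pc$points) == 0L) stop("cannot normalize an empty cloud")
  center <- colMeans(pc$points)
  centered <- sweep(pc$points, 2L, center)
  scale <- sqrt(max(rowSums(centered^2)))
  if (scale < 1e-9) stop("degenerate cloud: all points identical, scale undefined")
  list(cloud = point_cloud(centered / scale, pc$normals, pc$labels),
       transform = list(center = center, scale = scale))
}

#' Undo a [normalize_cloud()] transform
#'
#' @param pc normalized [point_cloud()].
#' @param transform list with `center` and `scale` as returned by
#'   [normalize_cloud()].
#' @return the denormalized [point_cloud()] in mm.
#' @export
denormalize_cloud <- function(pc, transform) {
  point_cloud(sweep(pc$points * transform$scale, 2L, transform$center, "+"),
              pc$normals, pc$labels)
}

# Apply a normalization transform to raw points (forward direction).
apply_norm_transform <- function(points, transform) {
  sweep(points, 2L, transform$center) / transform$scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- PLY --------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, offsets, type) {
  size <- ply_type_size[[type]]
  idx <- as.vector(t(outer(offsets, seq_len(size), `+`)))
  bytes <- raw[idx]
  n <- length(offsets)
  switch(type,
         char = , int8 = as.numeric(readBin(bytes, "integer", n, 1L, signed = TRUE)),
         uchar = , uint8 = as.numeric(readBin(bytes, "integer", n, 1L, signed = FALSE)),
         short = , int16 = as.numeric(readBin(bytes, "integer", n, 2L, signed = TRUE, endian = "little")),
         ushort = , uint16 = as.numeric(readBin(bytes, "integer", n, 2L, signed = FALSE, endian = "little")),
         int = , int32 = , uint = , uint32 =
           as.numeric(readBin(bytes, "integer", n, 4L, endian = "little")),
         float = , float32 = readBin(bytes, "double", n, 4L, endian = "little"),
         double = , float64 = readBin(bytes, "double", n, 8L, endian = "little"),
         stop(sprintf("unsupported PLY property type: %s", type)))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1L)
  if (!identical(magic, "ply")) stop(sprintf("%s: not a PLY file (bad magic line)", path))
  fmt <- NULL
  elements <- list()
  cur <- NULL
  lineno <- 1L
  repeat {
    line <- readLines(con, 1L)
    lineno <- lineno + 1L
    if (length(line) == 0L) stop(sprintf("%s: unexpected end of header at line %d", path, lineno))
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop(sprintf("%s: unsupported PLY format '%s' (line %d)", path, fmt, lineno))
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop(sprintf("%s: property before element (line %d)", path, lineno))
      if (tok[2L] == "list") {
        cur$props[[tok[5L]]] <- list(list = TRUE, ctype = tok[3L], itype = tok[4L])
      } else {
        cur$props[[tok[3L]]] <- list(list = FALSE, type = tok[2L])
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else stop(sprintf("%s: unrecognized header keyword '%s' (line %d)", path, tok[1L], lineno))
  }
  if (is.null(fmt)) stop(sprintf("%s: PLY header has no format line", path))

  out <- list(vertices = NULL, normals = NULL, labels = NULL, faces = NULL)
  if (fmt == "ascii") {
    body <- readLines(con)
    pos <- 0L
    for (el in elements) {
      if (el$count == 0L) next
      lines <- body[(pos + 1L):(pos + el$count)]
      pos <- pos + el$count
      toks <- strsplit(trimws(lines), "\\s+")
      if (el$name == "vertex") {
        m <- do.call(rbind, lapply(toks, as.numeric))
        out <- ply_collect_vertex(out, m, names(el$props))
      } else if (el$name == "face") {
        faces <- lapply(toks, function(tk) {
          cnt <- as.integer(tk[1L])
          if (cnt != 3L) stop(sprintf("%s: non-triangular face (count %d)", path, cnt))
          as.integer(tk[2:4])
        })
        out$faces <- do.call(rbind, faces) + 1L
      }
    }
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    off <- 0L
    for (el in elements) {
      prop_list <- vapply(el$props, function(p) p$list, logical(1))
      if (el$name == "vertex" || !any(prop_list)) {
        sizes <- vapply(names(el$props), function(nm) ply_type_size[[el$props[[nm]]$type]], integer(1))
        rec <- sum(sizes)
        starts <- off + (seq_len(el$count) - 1L) * rec
        cols <- list()
        po <- 0L
        for (nm in names(el$props)) {
          cols[[nm]] <- ply_read_scalar(raw, starts + po, el$props[[nm]]$type)
          po <- po + ply_type_size[[el$props[[nm]]$type]]
        }
        off <- off + el$count * rec
        if (el$name == "vertex")
          out <- ply_collect_vertex(out, do.call(cbind, cols), names(el$props))
      } else {
        # face element with a single list property of uniform count 3
        p <- el$props[[which(prop_list)[1L]]]
        csz <- ply_type_size[[p$ctype]]; isz <- ply_type_size[[p$itype]]
        counts <- ply_read_scalar(raw, off + (seq_len(el$count) - 1L) * (csz + 3L * isz), p$ctype)
        if (!all(counts == 3L)) {
          # variable-length fallback: walk records one by one
          faces <- matrix(0L, 0L, 3L)
          cur_off <- off
          for (i in seq_len(el$count)) {
            cnt <- ply_read_scalar(raw, cur_off, p$ctype)
            if (cnt != 3L) stop(sprintf("%s: non-triangular face at byte %d", path, cur_off))
            idx <- vapply(0:2, function(k) ply_read_scalar(raw, cur_off + csz + k * isz, p$itype), numeric(1))
            faces <- rbind(faces, as.integer(idx))
            cur_off <- cur_off + csz + cnt * isz
          }
          off <- cur_off
          out$faces <- faces + 1L
        } else {
          rec <- csz + 3L * isz
          starts <- off + (seq_len(el$count) - 1L) * rec
          f <- vapply(0:2, function(k) ply_read_scalar(raw, starts + csz + k * isz, p$itype),
                      numeric(el$count))
          if (el$count == 1L) f <- matrix(f, 1L)
          off <- off + el$count * rec
          out$faces <- matrix(as.integer(f), ncol = 3L) + 1L
        }
      }
    }
  }
  if (is.null(out$vertices)) stop(sprintf("%s: PLY has no vertex element", path))
  out
}

ply_collect_vertex <- function(out, m, prop_names) {
  colnames(m) <- prop_names
  need <- c("x", "y", "z")
  if (!all(need %in% prop_names)) stop("PLY vertex element lacks x/y/z properties")
  out$vertices <- unname(m[, need, drop = FALSE])
  if (all(c("nx", "ny", "nz") %in% prop_names))
    out$normals <- unname(m[, c("nx", "ny", "nz"), drop = FALSE])
  if ("label" %in% prop_names)
    out$labels <- paste0("L", as.integer(m[, "label"]))
  out
}

write_ply <- function(path, vertices, faces = NULL, normals = NULL,
                      labels = NULL, binary = FALSE) {
  n <- nrow(vertices)
  has_n <- !is.null(normals)
  has_l <- !is.null(labels)
  label_int <- if (has_l) as.integer(sub("^L", "", labels)) else NULL
  if (has_l && any(is.na(label_int)))
    stop("labels must be vertebra level tags of the form 'L<k>' to persist in PLY")
  header <- c("ply",
              sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              if (has_n) c("property double nx", "property double ny", "property double nz"),
              if (has_l) "property int label",
              if (!is.null(faces)) c(sprintf("element face %d", nrow(faces)),
                                     "property list uchar int vertex_indices"),
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(vertices[i, ]), con, size = 8L, endian = "little")
      if (has_n) writeBin(as.numeric(normals[i, ]), con, size = 8L, endian = "little")
      if (has_l) writeBin(label_int[i], con, size = 4L, endian = "little")
    }
    if (!is.null(faces)) {
      f0 <- faces - 1L
      for (i in seq_len(nrow(faces))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
      }
    }
  } else {
    m <- vertices
    if (has_n) m <- cbind(m, normals)
    rows <- apply(format(m, digits = 17, scientific = FALSE, trim = TRUE), 1L, paste, collapse = " ")
    if (has_l) rows <- paste(rows, label_int)
    writeLines(rows, con, sep = "\n")
    if (!is.null(faces)) {
      f0 <- faces - 1L
      writeLines(paste(3L, f0[, 1L], f0[, 2L], f0[, 3L]), con, sep = "\n")
    }
  }
  invisible(path)
}

# ---- OBJ --------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vt <- grepl("^v\\s", lines)
  ft <- grepl("^f\\s", lines)
  if (!any(vt)) stop(sprintf("%s: OBJ has no vertex lines", path))
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", lines[vt])), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  if (any(is.na(verts)))
    stop(sprintf("%s: malformed vertex line (line %d)",
                 path, which(vt)[which(is.na(rowSums(verts)))[1L]]))
  faces <- NULL
  if (any(ft)) {
    faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", lines[ft])), "\\s+"), function(x) {
      if (length(x) != 3L) stop(sprintf("%s: only triangular OBJ faces are supported", path))
      as.integer(vapply(strsplit(x, "/"), `[[`, character(1), 1L))
    }))
  }
  triangle_mesh(verts, faces %||% matrix(integer(), 0L, 3L))
}

write_obj <- function(path, mesh) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- format(mesh$vertices, digits = 17, scientific = FALSE, trim = TRUE)
  writeLines(paste("v", v[, 1L], v[, 2L], v[, 3L]), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(paste("f", mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
  invisible(path)
}

# ---- STL --------------------------------------------------------------------

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 count + 50-byte records
  sz <- file.size(path)
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    cnt <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (!is.na(cnt) && sz == 84 + 50 * cnt) is_binary <- TRUE
  }
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    tris <- matrix(0, 3L * cnt, 3L)
    for (i in seq_len(cnt)) {
      rec <- readBin(con, "double", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)
      tris[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop(sprintf("%s: malformed ASCII STL (vertex count %d not divisible by 3)",
                   path, length(vl)))
    tris <- do.call(rbind, lapply(strsplit(trimws(lines[vl]), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  }
  # weld exactly coincident vertices so shared edges are shared indices
  key <- apply(tris, 1L, paste, collapse = "|")
  uniq <- !duplicated(key)
  verts <- tris[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  keep <- faces[, 1L] != faces[, 2L] & faces[, 1L] != faces[, 3L] & faces[, 2L] != faces[, 3L]
  triangle_mesh(verts, faces[keep, , drop = FALSE])
}

write_stl_ascii <- function(path, mesh) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- v[mesh$faces[i, ], , drop = FALSE]
    n <- cross3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[1L], n[2L], n[3L]), con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %.17g %.17g %.17g", tri[, 1L], tri[, 2L], tri[, 3L]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}
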