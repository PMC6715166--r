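#' @useDynLib shellmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median prcomp quantile sd var wilcox.test ks.test p.adjust
#'   rnorm runif rlnorm rgamma setNames dist
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# TriangleMesh: vertices (n x 3, mm) + faces (m x 3, 1-based indices)
# ---------------------------------------------------------------------------

#' Construct a triangle mesh
#'
#' A minimal indexed triangle-mesh container for valve surfaces: an `n x 3`
#' vertex matrix (coordinates in mm by default) and an `m x 3` integer face
#' matrix of 1-based vertex indices. Faces are assumed consistently wound
#' (outward normals for closed solids); degenerate faces below an area
#' threshold are dropped.
#'
#' @param vertices numeric matrix, `n x 3`.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param units length unit tag, default `"mm"`.
#' @param degenerate_area faces with area below this (mm^2) are removed;
#'   default `1e-12`, chosen for numerical stability of signed volumes.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, units = "mm", degenerate_area = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) == 0L || nrow(vertices) == 0L) stop("empty mesh")
  if (max(faces) > nrow(vertices) || min(faces) < 1L)
    stop("face index out of range")
  m <- structure(list(vertices = vertices, faces = faces, units = units),
                 class = "triangle_mesh")
  areas <- face_areas(m)
  if (any(areas < degenerate_area)) {
    m$faces <- m$faces[areas >= degenerate_area, , drop = FALSE]
    if (nrow(m$faces) == 0L) stop("all faces degenerate")
  }
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces [%s]%s\n",
              nrow(x$vertices), nrow(x$faces), x$units,
              if (is_closed_mesh(x)) ", closed" else ", open"))
  invisible(x)
}

#' Per-face areas of a triangle mesh
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of face areas.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area
#' @param mesh a `triangle_mesh`.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

# undirected edge table: one row per face edge, key = "lo_hi"
mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  paste(lo, hi, sep = "_")
}

#' Test whether a mesh is a closed surface
#'
#' Closed means every undirected edge is shared by exactly two faces.
#' @param mesh a `triangle_mesh`.
#' @export
is_closed_mesh <- function(mesh) {
  all(table(mesh_edge_keys(mesh$faces)) == 2L)
}

#' Boundary vertex indices of an open mesh
#'
#' Vertices incident to edges used by exactly one face, in no particular
#' order. Empty for a closed mesh.
#' @param mesh a `triangle_mesh`.
#' @export
boundary_vertices <- function(mesh) {
  keys <- mesh_edge_keys(mesh$faces)
  tab <- table(keys)
  bkeys <- names(tab)[tab == 1L]
  if (length(bkeys) == 0L) return(integer(0))
  idx <- unique(as.integer(unlist(strsplit(bkeys, "_", fixed = TRUE))))
  sort(idx)
}

median_edge_length <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  d <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  stats::median(d)
}

# ---------------------------------------------------------------------------
# STL input/output
# ---------------------------------------------------------------------------

#' Load a valve surface mesh from an STL file
#'
#' Reads binary or ASCII STL (auto-detected), merges duplicate vertices and
#' validates the result. OBJ and PLY (ASCII) files are accepted through the
#' same contract, dispatched on the file extension.
#'
#' @param path path to the mesh file.
#' @param units length unit tag attached to the mesh, default `"mm"`.
#' @return a validated `triangle_mesh`.
#' @export
load_valve_mesh <- function(path, units = "mm") {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tri <- switch(ext,
                obj = read_obj_tri(path),
                ply = read_ply_tri(path),
                read_stl_tri(path))
  if (is.null(tri) || nrow(tri$vertices) == 0L || nrow(tri$faces) == 0L)
    stop("no triangles found in ", path)
  m <- triangle_mesh(tri$vertices, tri$faces, units = units)
  message(sprintf("loaded %s: %d vertices, %d faces",
                  basename(path), nrow(m$vertices), nrow(m$faces)))
  m
}

# STL stores one vertex triple per facet; weld exact duplicates
weld_vertices <- function(coords) {
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = "|")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  nf <- nrow(coords) / 3L
  list(vertices = coords[first, , drop = FALSE],
       faces = matrix(idx, nrow = nf, ncol = 3L, byrow = TRUE))
}

read_stl_tri <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = min(84, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    nfac <- readBin(header[81:84], "integer", size = 4, endian = "little")
    if (!is.na(nfac) && nfac > 0 && sz == 84 + 50 * as.numeric(nfac)) is_binary <- TRUE
  }
  if (is_binary) {
    nfac <- readBin(header[81:84], "integer", size = 4, endian = "little")
    body <- readBin(con, "raw", n = 50 * nfac)
    m <- matrix(body, nrow = 50)
    coords <- matrix(0, nrow = 3L * nfac, ncol = 3L)
    for (k in 0:2) {  # three vertices per facet; skip 12-byte normal
      off <- 12 + 12 * k
      vals <- readBin(as.vector(m[(off + 1):(off + 12), ]), "numeric",
                      size = 4, n = 3L * nfac, endian = "little")
      vm <- matrix(vals, ncol = 3L, byrow = TRUE)
      coords[seq(k + 1L, by = 3L, length.out = nfac), ] <- vm
    }
    return(weld_vertices(coords))
  }
  # ASCII
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("not a parseable STL file (no complete facets): ", path)
  nums <- lapply(strsplit(trimws(vlines), "\\s+"),
                 function(p) as.numeric(p[2:4]))
  coords <- do.call(rbind, nums)
  if (anyNA(coords)) stop("malformed vertex line in ", path)
  weld_vertices(coords)
}

read_obj_tri <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    as.integer(vapply(strsplit(p[2:4], "/"), `[`, "", 1L))
  }))
  list(vertices = verts, faces = faces)
}

read_ply_tri <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("ascii", txt[2])) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", txt, value = TRUE)[1]))
  start <- which(txt == "end_header")[1]
  vrows <- txt[(start + 1):(start + nv)]
  frows <- txt[(start + nv + 1):(start + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vrows), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(frows), "\\s+"),
                                 function(p) as.integer(p[2:4]) + 1L))
  list(vertices = verts, faces = faces)
}

#' Write a mesh as binary STL
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  nrm <- sqrt(nx^2 + ny^2 + nz^2); nrm[nrm == 0] <- 1
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(nx[i], ny[i], nz[i]) / nrm[i]),
             con, size = 4, endian = "little")
    writeBin(as.numeric(t(v[f[i, ], ])), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cleanup
# ---------------------------------------------------------------------------

#' Keep the largest connected component of a mesh
#'
#' Components are connected through shared vertices; the component with the
#' largest total surface area is kept (ties broken deterministically by the
#' lowest minimum vertex index). Emulates the automatic removal of isolated
#' debris parts from scan meshes.
#'
#' @param mesh a `triangle_mesh`.
#' @return a `triangle_mesh` containing only the largest component.
#' @export
clean_largest_component <- function(mesh) {
  f <- mesh$faces
  g <- igraph::graph_from_edgelist(
    rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  fcomp <- comp[f[, 1]]
  areas <- face_areas(mesh)
  carea <- tapply(areas, fcomp, sum)
  best <- max(carea)
  cand <- as.integer(names(carea)[carea >= best - 1e-12 * max(best, 1)])
  if (length(cand) > 1L) {  # tie-break: lowest minimum vertex index
    minv <- vapply(cand, function(cc) min(f[fcomp == cc, ]), 0L)
    cand <- cand[which.min(minv)]
  }
  keep <- fcomp == cand[1]
  n_removed <- length(unique(fcomp)) - 1L
  if (n_removed > 0L)
    message(sprintf("removed %d isolated component(s)", n_removed))
  if (!any(keep)) stop("all components degenerate")
  subset_mesh_faces(mesh, which(keep))
}

# restrict mesh to a face subset, reindexing vertices; keeps a map attribute
subset_mesh_faces <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  out <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(remap[f], ncol = 3L), units = mesh$units)
  attr(out, "orig_vertex_index") <- used
  out
}

# ---------------------------------------------------------------------------
# Surface sampling
# ---------------------------------------------------------------------------

#' Strict Poisson-disk sampling of a mesh surface
#'
#' Places exactly `n` points on the surface by dart throwing under an
#' exclusion radius, relaxing the radius geometrically until the requested
#' count fits. The initial radius is a fraction of the ideal hexagonal
#' packing spacing for the surface area, so accepted points are close to
#' evenly spaced. Reproducible under `set.seed()`.
#'
#' @param mesh a `triangle_mesh` with positive area.
#' @param n number of points (>= 1); the shell-thickness and body-size
#'   procedures use 100,000.
#' @param seed integer seed applied before sampling (logged); default 0.
#' @param r0_frac starting radius as a fraction of the hexagonal packing
#'   spacing `sqrt(2A / (sqrt(3) n))`; default 0.75.
#' @param relax radius relaxation factor per failed round; default 0.9.
#' @return an object of class `point_cloud`: list with `points` (`n x 3`),
#'   `face` (source triangle of each point), `radius` (final exclusion
#'   radius) and `source` tag.
#' @export
poisson_disk_points <- function(mesh, n, seed = 0L, r0_frac = 0.75, relax = 0.9) {
  stopifnot(n >= 1)
  areas <- face_areas(mesh)
  total <- sum(areas)
  if (!(total > 0)) stop("mesh has zero surface area")
  r0 <- r0_frac * sqrt(2 * total / (sqrt(3) * n))
  set.seed(as.integer(seed))
  res <- cpp_poisson_disk(mesh$vertices, mesh$faces - 1L, cumsum(areas),
                          as.integer(n), r0, relax, as.integer(max(2000L, 30L * n)))
  structure(list(points = res$points, face = res$face, radius = res$radius,
                 source = "whole", seed = as.integer(seed)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points (%s), exclusion radius %.4g\n",
              nrow(x$points), x$source, x$radius))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Geometric primitives
# ---------------------------------------------------------------------------

#' Signed-tetrahedra (cone) volume of a surface
#'
#' Sum over faces of the signed volume of the tetrahedron spanned by the face
#' and an apex point. For a closed, consistently outward-wound surface the
#' sum is independent of the apex and equals the enclosed volume (positive
#' sign). For an open surface it is the volume of the cone solid obtained by
#' capping the boundary with the fan of triangles to the apex.
#'
#' @param surface a `triangle_mesh`.
#' @param apex numeric length-3 apex point; default the origin.
#' @param check_winding if `TRUE` (default) and the surface is closed, the
#'   apex-shift invariance is verified and a warning with both values is
#'   raised when it fails (inconsistent winding).
#' @return volume in cubic mesh units (mm^3).
#' @export
cone_volume <- function(surface, apex = c(0, 0, 0), check_winding = TRUE) {
  stopifnot(length(apex) == 3, all(is.finite(apex)))
  v <- surface$vertices; f <- surface$faces
  vol_at <- function(a) {
    p1 <- sweep(v[f[, 1], , drop = FALSE], 2, a)
    p2 <- sweep(v[f[, 2], , drop = FALSE], 2, a)
    p3 <- sweep(v[f[, 3], , drop = FALSE], 2, a)
    sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
        p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
        p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  }
  vol <- vol_at(apex)
  if (check_winding && is_closed_mesh(surface)) {
    shift <- apex + max(1, diff(range(v))) * c(1, 0.5, 0.25)
    vol2 <- vol_at(shift)
    tol <- 1e-8 * max(1, abs(vol))
    if (abs(vol - vol2) > tol)
      warning(sprintf(
        "closed surface volume changes with apex (%.6g vs %.6g): inconsistent winding",
        vol, vol2))
  }
  vol
}

#' Centroid size of a point set
#'
#' The square root of the sum of squared distances of each point from the
#' centroid of the points: the standard geometric-morphometric size measure.
#' Invariant to rotation and translation; scales linearly under isotropic
#' scaling.
#'
#' @param points a `point_cloud`, a `triangle_mesh` (its vertices are used),
#'   or an `n x 3` matrix.
#' @return centroid size (mm).
#' @export
centroid_size <- function(points) {
  p <- as_points3(points)
  ctr <- colMeans(p)
  sqrt(sum(sweep(p, 2, ctr)^2))
}

as_points3 <- function(x) {
  if (inherits(x, "point_cloud")) return(x$points)
  if (inherits(x, "triangle_mesh")) return(x$vertices)
  p <- as.matrix(x)
  if (ncol(p) != 3L) stop("expected 3D points")
  storage.mode(p) <- "double"
  p
}
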