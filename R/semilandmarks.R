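# Internal-surface semilandmark gridding: plane sections along the
# beak-to-ventral axis, "flat-sorting" of the section points in the plane of
# the commissure, 1%-spaced subsampling, and generalized Procrustes
# superimposition of the resulting 100 x 101 grids.

unit <- function(v) v / sqrt(sum(v^2))

#' Flat-sort section points
#'
#' Orders the candidate intersection points of one sampling plane by first
#' projecting them onto the XY plane of the common frame (Z set to 0),
#' then sorting by increasing projected Euclidean distance to the reference
#' "anteriormost" point (the candidate with the largest coordinate along the
#' anterior direction). This projected sort stays stable across recurved or
#' overhanging surface features where a sort on 3D distances inverts.
#'
#' @param points `k x 3` matrix of candidate points (common frame).
#' @param anterior_dir in-plane direction toward the anterior corner of the
#'   frame, default `c(1, 1, 0)`.
#' @return list with `order` (permutation of rows), `ref` (index of the
#'   reference point) and `dist` (projected distances, in `order`).
#' @export
flat_sort_section <- function(points, anterior_dir = c(1, 1, 0)) {
  P <- as_points3(points)
  flat <- P; flat[, 3] <- 0
  a <- unit(anterior_dir)
  ref <- which.max(flat %*% a)
  d <- sqrt(rowSums(sweep(flat, 2, flat[ref, ])^2))
  ord <- order(d)  # stable: ties keep input index order
  list(order = ord, ref = ref, dist = d[ord])
}

# plane/mesh intersection: returns candidate points on the loop containing
# the anteriormost point, densified so at least min_candidates exist
section_candidates <- function(mesh, section_point, axis, anterior_dir = c(1, 1, 0),
                               min_candidates = 202L) {
  v <- mesh$vertices
  ax <- unit(axis)
  d <- as.vector(sweep(v, 2, section_point) %*% ax)
  scale <- max(abs(d), 1e-9)
  if (any(abs(d) < 1e-12 * scale)) {
    # nudge the plane so no vertex lies exactly on it (deterministic)
    d <- d - 1e-9 * scale
  }
  f <- mesh$faces
  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  crossed <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossed)) return(NULL)
  fc <- f[crossed, , drop = FALSE]
  # per crossed face: the two edges with a sign change give a segment
  segs <- vector("list", nrow(fc))
  edge_pts <- new.env(parent = emptyenv())  # key "lo_hi" -> point (shared)
  ipt <- function(i, j) {
    key <- paste(min(i, j), max(i, j), sep = "_")
    got <- edge_pts[[key]]
    if (!is.null(got)) return(got)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    assign(key, p, envir = edge_pts)
    p
  }
  for (k in seq_len(nrow(fc))) {
    tri <- fc[k, ]
    dd <- d[tri]
    pos <- tri[dd > 0]; neg <- tri[dd < 0]
    solo <- if (length(pos) == 1L) pos else neg
    other <- setdiff(tri, solo)
    segs[[k]] <- rbind(ipt(solo, other[1]), ipt(solo, other[2]))
  }
  pts <- do.call(rbind, segs)           # 2 per face-segment, with duplicates
  seg_id <- rep(seq_along(segs), each = 2L)
  # identify the loop containing the anteriormost candidate: chain segments
  key <- paste(round(pts[, 1], 9), round(pts[, 2], 9), round(pts[, 3], 9))
  uk <- unique(key)
  node <- match(key, uk)
  g <- igraph::graph_from_edgelist(matrix(node, ncol = 2L, byrow = TRUE),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  flat <- pts; flat[, 3] <- 0
  amax <- which.max(flat %*% unit(anterior_dir))
  keep_comp <- comp[node[amax]]
  keep_seg <- comp[node[seq(1L, length(node), by = 2L)]] == keep_comp
  segs <- segs[keep_seg]
  # candidates: unique segment endpoints; densify by midpoint refinement
  cand <- unique(do.call(rbind, segs))
  while (nrow(cand) < min_candidates) {
    segs <- unlist(lapply(segs, function(s) {
      mid <- (s[1, ] + s[2, ]) / 2
      list(rbind(s[1, ], mid), rbind(mid, s[2, ]))
    }), recursive = FALSE)
    cand <- unique(do.call(rbind, segs))
    if (length(segs) > 1e6) break
  }
  dimnames(cand) <- NULL
  cand
}

#' Semilandmarks from one sampling plane
#'
#' Intersects the plane through `section_point` perpendicular to `axis` with
#' the mesh edges, keeps the intersection loop containing the anteriormost
#' point (densified with midpoints when candidates are sparse), flat-sorts
#' the candidates, and subsamples them at 0%, 1%, ..., 100% of the maximum
#' projected distance from the reference point. Each selected point keeps
#' its original Z coordinate (points are selected, not interpolated).
#'
#' @param mesh aligned interior `triangle_mesh` (common frame).
#' @param section_point 3D point on the sampling axis.
#' @param axis sampling direction (beak to ventral), need not be unit.
#' @param n_sub number of semilandmarks per section, default 101.
#' @param anterior_dir see [flat_sort_section()].
#' @return `n_sub x 3` matrix of ordered surface points, or `NULL` when the
#'   plane misses the mesh.
#' @export
section_semilandmarks <- function(mesh, section_point, axis, n_sub = 101L,
                                  anterior_dir = c(1, 1, 0)) {
  cand <- section_candidates(mesh, section_point, axis, anterior_dir,
                             min_candidates = 2L * n_sub)
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  pick_semilandmarks(cand, n_sub, anterior_dir)
}

pick_semilandmarks <- function(cand, n_sub, anterior_dir = c(1, 1, 0)) {
  fs <- flat_sort_section(cand, anterior_dir)
  sorted <- cand[fs$order, , drop = FALSE]
  dmax <- fs$dist[length(fs$dist)]
  targets <- seq(0, 1, length.out = n_sub) * dmax
  idx <- findInterval(targets, fs$dist, all.inside = TRUE)
  # nearest candidate to each target distance (findInterval gives the left)
  right <- pmin(idx + 1L, length(fs$dist))
  use_right <- (fs$dist[right] - targets) < (targets - fs$dist[idx])
  sel <- ifelse(use_right, right, idx)
  sorted[sel, , drop = FALSE]
}

#' Build the 100 x 101 semilandmark grid of an aligned valve interior
#'
#' The sampling axis runs from the beak landmark to the ventral landmark;
#' sampling planes perpendicular to it are placed at 1%, 2%, ..., 100% of
#' its magnitude, and each contributes 101 flat-sorted semilandmarks, for
#' exactly 10,100 points. The final (100%) plane passes through the ventral
#' point and usually degenerates; available points are padded by repetition
#' (flagged in the `degenerate_sections` attribute).
#'
#' @param valve an `aligned_valve` whose `mesh` is the interior surface.
#' @param n_sections number of sampling planes, default 100.
#' @param n_sub semilandmarks per section, default 101.
#' @param specimen_id optional identifier stored with the grid.
#' @return an object of class `semilandmark_grid`: `points`
#'   (`n_sections*n_sub x 3`), `section` (index per point), `specimen_id`.
#' @export
build_semilandmark_grid <- function(valve, n_sections = 100L, n_sub = 101L,
                                    specimen_id = NULL) {
  stopifnot(inherits(valve, "aligned_valve"))
  beak <- valve$quarters$beak; ventral <- valve$quarters$ventral
  vec <- ventral - beak
  if (sqrt(sum(vec^2)) < 1e-9) stop("beak and ventral landmarks coincide")
  sections <- vector("list", n_sections)
  degenerate <- integer(0)
  for (s in seq_len(n_sections)) {
    frac <- s / n_sections
    p0 <- beak + frac * vec
    pts <- section_semilandmarks(valve$mesh, p0, vec, n_sub)
    if (is.null(pts)) {
      if (s == n_sections) {
        # terminal plane through the ventral point: degenerate by construction
        pts <- matrix(rep(ventral, n_sub), ncol = 3L, byrow = TRUE)
        degenerate <- c(degenerate, s)
      } else {
        stop(sprintf("empty mesh section at %d%% of the sampling axis", s))
      }
    }
    sections[[s]] <- pts
  }
  pts <- do.call(rbind, sections)
  structure(list(points = pts,
                 section = rep(seq_len(n_sections), each = n_sub),
                 n_sections = n_sections, n_sub = n_sub,
                 specimen_id = specimen_id,
                 degenerate_sections = degenerate),
            class = "semilandmark_grid")
}

#' @export
print.semilandmark_grid <- function(x, ...) {
  cat(sprintf("semilandmark_grid%s: %d points (%d sections x %d)\n",
              if (is.null(x$specimen_id)) "" else paste0(" [", x$specimen_id, "]"),
              nrow(x$points), x$n_sections, x$n_sub))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Generalized Procrustes superimposition on the four fixed landmarks
# ---------------------------------------------------------------------------

#' Procrustes superimposition of semilandmark grids on their fixed landmarks
#'
#' Generalized Procrustes analysis (translation, rotation and, by default,
#' scaling) iterated on each specimen's four fixed landmarks (beak,
#' anterior, ventral, posterior) until the consensus stabilizes; each
#' specimen's full semilandmark grid is then carried into the Procrustes
#' frame by that specimen's fitted similarity transform.
#'
#' @param grids list of `semilandmark_grid` objects (or `n x 3` matrices).
#' @param fixed list of `quarter_landmarks` (or `4 x 3` matrices), parallel
#'   to `grids`.
#' @param do_scale scale each configuration to unit centroid size (default
#'   `TRUE`); settable to `FALSE` to examine the interaction with the
#'   earlier commissure-size scaling.
#' @param tol convergence threshold on the consensus change, default 1e-10.
#' @return an object of class `procrustes_set`: `aligned` (list of aligned
#'   grid matrices), `fixed_aligned`, `consensus` (mean aligned fixed
#'   configuration), `mean_grid`, `transforms` (per-specimen list with
#'   `centroid`, `scale`, `rotation`), `specimen_ids`.
#' @export
gpa_align <- function(grids, fixed, do_scale = TRUE, tol = 1e-10) {
  n <- length(grids)
  if (n < 2L) stop("Procrustes superimposition needs at least 2 specimens")
  if (length(fixed) != n) stop("grids and fixed landmarks differ in length")
  ids <- vapply(seq_len(n), function(i) {
    g <- grids[[i]]
    if (inherits(g, "semilandmark_grid") && !is.null(g$specimen_id))
      as.character(g$specimen_id) else paste0("spec", i)
  }, "")
  G <- lapply(grids, function(g)
    if (inherits(g, "semilandmark_grid")) g$points else as_points3(g))
  FX <- lapply(fixed, function(q)
    if (inherits(q, "quarter_landmarks")) quarters_matrix(q) else as_points3(q))
  for (X in FX)
    if (qr(sweep(X, 2, colMeans(X)))$rank < 2L)
      stop("collinear fixed landmarks: Procrustes rotation underdetermined")
  cen <- lapply(FX, colMeans)
  Xc <- lapply(seq_len(n), function(i) sweep(FX[[i]], 2, cen[[i]]))
  beta <- vapply(Xc, function(X) {
    cs <- sqrt(sum(X^2))
    if (!(cs > 0)) stop("degenerate fixed landmarks")
    if (do_scale) 1 / cs else 1
  }, 0)
  Xs <- lapply(seq_len(n), function(i) Xc[[i]] * beta[i])
  R <- rep(list(diag(3)), n)
  consensus <- Xs[[1]]
  repeat {
    for (i in seq_len(n)) R[[i]] <- rigid_fit(Xs[[i]], consensus)$R
    aligned <- lapply(seq_len(n), function(i) Xs[[i]] %*% t(R[[i]]))
    new_consensus <- Reduce(`+`, aligned) / n
    if (do_scale) {
      cs <- sqrt(sum(sweep(new_consensus, 2, colMeans(new_consensus))^2))
      new_consensus <- new_consensus / cs
    }
    if (max(abs(new_consensus - consensus)) < tol) { consensus <- new_consensus; break }
    consensus <- new_consensus
  }
  for (i in seq_len(n)) R[[i]] <- rigid_fit(Xs[[i]], consensus)$R
  fixed_aligned <- lapply(seq_len(n), function(i) Xs[[i]] %*% t(R[[i]]))
  aligned <- lapply(seq_len(n), function(i)
    (sweep(G[[i]], 2, cen[[i]]) * beta[i]) %*% t(R[[i]]))
  transforms <- lapply(seq_len(n), function(i)
    list(centroid = cen[[i]], scale = beta[i], rotation = R[[i]]))
  structure(list(aligned = aligned, fixed_aligned = fixed_aligned,
                 consensus = Reduce(`+`, fixed_aligned) / n,
                 mean_grid = Reduce(`+`, aligned) / n,
                 transforms = transforms, specimen_ids = ids,
                 do_scale = do_scale),
            class = "procrustes_set")
}

#' @export
print.procrustes_set <- function(x, ...) {
  cat(sprintf("procrustes_set: %d specimens, %d landmarks each%s\n",
              length(x$aligned), nrow(x$aligned[[1]]),
              if (x$do_scale) "" else " (no scaling)"))
  invisible(x)
}

#' Export semilandmark grids as a wide CSV
#'
#' One row per specimen: `specimen_id, x1, y1, z1, ..., x10100, y10100,
#' z10100`.
#' @param grids list of `semilandmark_grid` objects or matrices.
#' @param path output CSV path.
#' @param ids optional specimen ids.
#' @export
write_grid_csv <- function(grids, path, ids = NULL) {
  mats <- lapply(grids, function(g)
    if (inherits(g, "semilandmark_grid")) g$points else as_points3(g))
  if (is.null(ids))
    ids <- vapply(seq_along(grids), function(i) {
      g <- grids[[i]]
      if (inherits(g, "semilandmark_grid") && !is.null(g$specimen_id))
        as.character(g$specimen_id) else paste0("spec", i)
    }, "")
  flat <- t(vapply(mats, function(m) as.vector(t(m)), numeric(3 * nrow(mats[[1]]))))
  k <- nrow(mats[[1]])
  colnames(flat) <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                                      function(i, a) paste0(a, i))))
  df <- data.frame(specimen_id = ids, flat, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export one grid in a plain landmark-file format
#'
#' Header line `LM3=<count>` followed by one `x y z` point per line, for
#' interoperability with standard morphometrics software.
#' @param grid a `semilandmark_grid` or matrix.
#' @param path output path.
#' @export
write_landmark_file <- function(grid, path) {
  m <- if (inherits(grid, "semilandmark_grid")) grid$points else as_points3(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LM3=%d", nrow(m)), con)
  writeLines(apply(format(m, digits = 10, trim = TRUE), 1, paste, collapse = " "), con)
  invisible(path)
}
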