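# Commissure handling, interior/exterior splitting, the four fixed landmarks,
# commissure-centroid-size scaling and rigid frame alignment.

#' Construct a commissure curve
#'
#' An ordered, closed 3D polyline digitized along the valve margin. The curve
#' defines the interior/exterior split of the valve surface and anchors the
#' four fixed landmarks (beak, anterior, ventral, posterior).
#'
#' @param points `n x 3` matrix of ordered coordinates (mm). If the first and
#'   last points coincide the duplicate is dropped; closure is implied.
#' @param beak_index index of the curve point closest to the shell beak
#'   (manual landmark); default 1.
#' @param gap_tol maximum endpoint gap, as a fraction of total arc length,
#'   accepted for an implicitly closed curve; default 0.05.
#' @return an object of class `commissure_curve`.
#' @export
commissure_curve <- function(points, beak_index = 1L, gap_tol = 0.05) {
  p <- as_points3(points)
  if (nrow(p) >= 2 && sqrt(sum((p[1, ] - p[nrow(p), ])^2)) < 1e-12)
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 4L) stop("commissure curve needs at least 4 distinct points")
  seg <- sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2))
  L <- sum(seg)
  if (!(L > 0)) stop("commissure curve has zero arc length")
  # the closing segment is an endpoint gap (not implied closure) when it is
  # both a large fraction of the arc and far longer than a typical segment
  gap <- seg[length(seg)]
  if (gap > gap_tol * L && gap > 3 * stats::median(seg[-length(seg)]))
    stop(sprintf("curve endpoint gap (%.3g) exceeds %.0f%% of arc length", gap, 100 * gap_tol))
  beak_index <- as.integer(beak_index)
  if (beak_index < 1L || beak_index > nrow(p)) stop("beak_index out of range")
  structure(list(points = p, beak_index = beak_index), class = "commissure_curve")
}

#' @export
print.commissure_curve <- function(x, ...) {
  cat(sprintf("commissure_curve: %d points, beak at index %d\n",
              nrow(x$points), x$beak_index))
  invisible(x)
}

#' Read a commissure curve from CSV
#'
#' Expects ordered rows `x,y,z` (mm), optional header, and an optional fourth
#' integer column flagging the beak row with a nonzero value.
#'
#' @param path CSV file path.
#' @return a `commissure_curve`.
#' @export
read_commissure_csv <- function(path) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (all(is.na(suppressWarnings(as.numeric(raw[1, 1:3]))))) {
    raw <- raw[-1, , drop = FALSE]  # header row
  }
  xyz <- apply(raw[, 1:3, drop = FALSE], 2, as.numeric)
  beak <- 1L
  if (ncol(raw) >= 4) {
    flag <- suppressWarnings(as.integer(raw[, 4]))
    hit <- which(!is.na(flag) & flag != 0L)
    if (length(hit)) beak <- hit[1]
  }
  commissure_curve(xyz, beak_index = beak)
}

# cumulative arc length positions of polyline vertices (closed), length n+1
cum_arclength <- function(p) {
  seg <- sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2))
  c(0, cumsum(seg))
}

# linear interpolation along a closed polyline at arclength s in [0, L)
interp_closed <- function(p, cums, s) {
  L <- cums[length(cums)]
  s <- s %% L
  i <- findInterval(s, cums, rightmost.closed = TRUE)
  i <- pmin(i, nrow(p))
  t <- (s - cums[i]) / pmax(cums[i + 1] - cums[i], .Machine$double.eps)
  nxt <- c(2:nrow(p), 1)
  p[i, , drop = FALSE] + (p[nxt[i], , drop = FALSE] - p[i, , drop = FALSE]) * t
}

#' Quarter landmarks and arc-length resampling of a commissure curve
#'
#' Normalizes the traversal direction to clockwise, resamples the closed
#' curve to `n_resample` points equally spaced by cumulative Euclidean
#' distance starting at the beak-closest point, and returns the four fixed
#' landmarks at 0, 25, 50 and 75 percent of the cumulative clockwise
#' distance: beak, anterior, ventral and posterior.
#'
#' "Clockwise" is judged looking against `view_normal` (i.e. from outside the
#' valve): the signed area of the curve projected on its best-fit plane,
#' with the plane normal signed to agree with `view_normal`, must be
#' negative; the traversal is flipped otherwise. The input traversal
#' direction and starting index therefore do not affect the result.
#'
#' @param curve a `commissure_curve`.
#' @param n_resample number of equally spaced points, default 75 (the count
#'   whose centroid size scales the valve).
#' @param view_normal direction from which the valve is viewed from outside;
#'   default `c(0, 0, 1)`, appropriate for a left valve digitized with its
#'   bowl opening toward +z. For a right valve digitized the same way, pass
#'   `c(0, 0, -1)` (or use `side = "right"`), so that the anterior/posterior
#'   labels stay anatomically consistent and a mirror pair aligns onto the
#'   same configuration after right-valve mirroring.
#' @param side convenience switch: `"right"` flips `view_normal`.
#' @param reference_point optional 3D point on the convex (outer) side of the
#'   commissure plane, e.g. the valve mesh centroid; when given it replaces
#'   `view_normal`, making the result invariant under rigid motions of the
#'   digitized valve.
#' @return a list of class `quarter_landmarks`: `beak`, `anterior`,
#'   `ventral`, `posterior` (3-vectors), plus `resampled` (`n_resample x 3`
#'   clockwise arc-length resample starting at the beak) and
#'   `centroid_size` of the resample.
#' @export
quarter_landmarks <- function(curve, n_resample = 75L, view_normal = c(0, 0, 1),
                              side = c("left", "right"),
                              reference_point = NULL) {
  side <- match.arg(side)
  if (!is.null(reference_point))
    view_normal <- reference_point - colMeans(curve$points)
  if (side == "right") view_normal <- -view_normal
  p <- curve$points
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q, nu = 0)
  nrm <- sv$v[, 3]
  if (sum(nrm * view_normal) < 0) nrm <- -nrm
  e1 <- sv$v[, 1]
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])  # e1 x e2 = -nrm ... fix below
  # ensure (e1, e2, nrm) right-handed: e2 = nrm x e1
  u <- q %*% e1
  v <- q %*% e2
  signed_area <- 0.5 * sum(u * v[c(2:length(v), 1)] - u[c(2:length(u), 1)] * v)
  if (signed_area > 0) {  # counter-clockwise as seen along -view_normal: flip
    p <- p[c(1, nrow(p):2), , drop = FALSE]
    curve$beak_index <- if (curve$beak_index == 1L) 1L else nrow(p) - curve$beak_index + 2L
  }
  # rotate so the beak point is first
  ord <- c(curve$beak_index:nrow(p), seq_len(curve$beak_index - 1L))
  p <- p[ord, , drop = FALSE]
  cums <- cum_arclength(p)
  L <- cums[length(cums)]
  res <- interp_closed(p, cums, L * (seq_len(n_resample) - 1) / n_resample)
  quarters <- interp_closed(p, cums, L * c(0, 0.25, 0.5, 0.75))
  structure(list(beak = quarters[1, ], anterior = quarters[2, ],
                 ventral = quarters[3, ], posterior = quarters[4, ],
                 resampled = res, centroid_size = centroid_size(res)),
            class = "quarter_landmarks")
}

#' @export
print.quarter_landmarks <- function(x, ...) {
  cat("quarter_landmarks (beak / anterior / ventral / posterior):\n")
  print(round(rbind(beak = x$beak, anterior = x$anterior,
                    ventral = x$ventral, posterior = x$posterior), 4))
  cat(sprintf("commissure centroid size (%d-point resample): %.4f\n",
              nrow(x$resampled), x$centroid_size))
  invisible(x)
}

quarters_matrix <- function(q) rbind(q$beak, q$anterior, q$ventral, q$posterior)

#' Split a valve mesh into interior and exterior surfaces at the commissure
#'
#' The commissure polyline is snapped to mesh vertices and completed into a
#' closed edge path by shortest paths along mesh edges; cutting the
#' face-adjacency graph along that path yields exactly two open surfaces.
#' The interior surface is the concave side: the one whose faces lie closer,
#' on average, to the valve's internal centroid.
#'
#' @param mesh a `triangle_mesh`.
#' @param curve a `commissure_curve` lying within tolerance of the surface.
#' @param snap_tol maximum allowed distance from curve points to the mesh, as
#'   a multiple of the median edge length; default 2 (robust to digitization
#'   jitter).
#' @return list with `interior` and `exterior` (`triangle_mesh`), plus the
#'   snapped closed vertex `path` (original vertex indices).
#' @export
split_at_commissure <- function(mesh, curve, snap_tol = 2) {
  v <- mesh$vertices; f <- mesh$faces
  mel <- median_edge_length(mesh)
  cp <- curve$points
  d2 <- cpp_nn_min_dist(cp, v)
  if (max(d2) > snap_tol * mel)
    stop(sprintf("commissure is not on the mesh surface: largest gap %.4g (tolerance %.4g)",
                 max(d2), snap_tol * mel))
  # snap each curve point to its nearest vertex
  snap <- vapply(seq_len(nrow(cp)), function(i) {
    which.min(colSums((t(v) - cp[i, ])^2))
  }, 0L)
  snap <- snap[c(TRUE, diff(snap) != 0L)]
  if (snap[length(snap)] == snap[1]) snap <- snap[-length(snap)]
  if (length(snap) < 3L) stop("commissure snaps to fewer than 3 distinct vertices")
  # edge graph with lengths
  eall <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(eall[, 1], eall[, 2]); hi <- pmax(eall[, 1], eall[, 2])
  ek <- !duplicated(paste(lo, hi))
  edges <- cbind(lo[ek], hi[ek])
  wts <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] - v[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(v) - igraph::vcount(g)))
  igraph::E(g)$weight <- wts
  # closed vertex path through consecutive snapped vertices
  path <- integer(0)
  nb <- length(snap)
  for (i in seq_len(nb)) {
    a <- snap[i]; b <- snap[if (i == nb) 1L else i + 1L]
    sp <- igraph::shortest_paths(g, from = a, to = b, output = "vpath")$vpath[[1]]
    sp <- as.integer(sp)
    if (length(sp) < 2L)
      stop("commissure cannot be embedded as a closed edge path (disconnected snap)")
    path <- c(path, sp[-length(sp)])
  }
  # cut faces apart across path edges
  pe <- cbind(path, c(path[-1], path[1]))
  pk <- paste(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]), sep = "_")
  # face adjacency via shared edges not on the path
  fkeys <- mesh_edge_keys(f)           # 3m keys, face = rep(1:m, 3)
  m <- nrow(f)
  fidx <- rep(seq_len(m), 3L)
  keep <- !(fkeys %in% pk)
  sp1 <- split(fidx[keep], fkeys[keep])
  adj <- do.call(rbind, lapply(sp1[lengths(sp1) == 2L], function(x) x))
  if (is.null(adj) || nrow(adj) == 0L) stop("mesh has no interior adjacency")
  fg <- igraph::graph_from_edgelist(adj, directed = FALSE)
  fg <- igraph::add_vertices(fg, max(0L, m - igraph::vcount(fg)))
  comp <- igraph::components(fg)
  if (comp$no != 2L)
    stop(sprintf("commissure cut produced %d components (expected 2); largest snap gap %.4g",
                 comp$no, max(d2)))
  side1 <- comp$membership == 1L
  # interior = side nearer the internal centroid of the whole valve
  ctr <- colMeans(v)
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  dctr <- sqrt(rowSums(sweep(fc, 2, ctr)^2))
  m1 <- mean(dctr[side1]); m2 <- mean(dctr[!side1])
  interior_faces <- if (m1 <= m2) which(side1) else which(!side1)
  exterior_faces <- if (m1 <= m2) which(!side1) else which(side1)
  list(interior = subset_mesh_faces(mesh, interior_faces),
       exterior = subset_mesh_faces(mesh, exterior_faces),
       path = path)
}

# closed-form rigid (rotation + translation) least-squares fit X -> Y (Kabsch)
rigid_fit <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  list(R = R, t = t)
}

apply_rigid <- function(P, fit) sweep(P %*% t(fit$R), 2, fit$t, `+`)

#' Scale and align a valve into the common reference frame
#'
#' Divides the mesh by the centroid size of the 75-point commissure resample,
#' then fits the four quarter landmarks by a rigid (rotation + translation,
#' no scaling) least-squares motion to the target square beak -> (0,0,0),
#' anterior -> (1,1,0), ventral -> (1,0,0), posterior -> (0,1,0). Right
#' valves are mirrored across the XY plane after alignment so every valve is
#' analyzed as a left valve.
#'
#' @param mesh a `triangle_mesh` (typically the interior surface).
#' @param quarters a `quarter_landmarks` for the same valve.
#' @param side `"left"` or `"right"`.
#' @return an object of class `aligned_valve`: `mesh` and `quarters` in the
#'   common frame, `scale_factor` (the commissure centroid size divided
#'   out), `mirrored` flag and the RMS `residual` of the four landmarks
#'   against their targets.
#' @export
orient_and_scale_valve <- function(mesh, quarters, side = c("left", "right")) {
  side <- match.arg(side)
  s <- quarters$centroid_size
  if (!(s > 0)) stop("commissure centroid size must be positive")
  Q <- quarters_matrix(quarters) / s
  if (qr(sweep(Q, 2, colMeans(Q)))$rank < 2L)
    stop("quarter landmarks are nearly collinear: rotation underdetermined")
  targets <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  # the crossed beak/anterior/ventral/posterior-to-corner correspondence makes
  # the fit roll-degenerate when the quarters have two mirror axes (perfect
  # circle or ellipse); warn, since the aligned roll is then arbitrary
  A <- crossprod(sweep(Q, 2, colMeans(Q)), sweep(targets, 2, colMeans(targets)))
  dsv <- svd(A, nu = 0, nv = 0)$d
  if (dsv[2] < 1e-6 * dsv[1])
    warning("commissure quarters are nearly bi-symmetric: aligned roll orientation is weakly determined")
  fit <- rigid_fit(Q, targets)
  Vm <- apply_rigid(mesh$vertices / s, fit)
  Qa <- apply_rigid(Q, fit)
  mirrored <- side == "right"
  faces <- mesh$faces
  if (mirrored) {
    Vm[, 3] <- -Vm[, 3]
    Qa[, 3] <- -Qa[, 3]
    faces <- faces[, c(1, 3, 2), drop = FALSE]  # keep winding consistent
  }
  out_mesh <- triangle_mesh(Vm, faces, units = paste0(mesh$units, "/Cs"))
  qa <- structure(list(beak = Qa[1, ], anterior = Qa[2, ], ventral = Qa[3, ],
                       posterior = Qa[4, ],
                       resampled = apply_rigid(quarters$resampled / s, fit),
                       centroid_size = 1),
                  class = "quarter_landmarks")
  structure(list(mesh = out_mesh, quarters = qa, scale_factor = s,
                 mirrored = mirrored,
                 residual = sqrt(mean((Qa - targets)^2))),
            class = "aligned_valve")
}

#' @export
print.aligned_valve <- function(x, ...) {
  cat(sprintf("aligned_valve: %d faces, scale factor %.4f, %smirrored, landmark RMS residual %.4g\n",
              nrow(x$mesh$faces), x$scale_factor,
              if (x$mirrored) "" else "not ", x$residual))
  invisible(x)
}

#' Read specimen metadata CSV
#'
#' One row per valve: `specimen_id, species, region, family,
#' functional_group, side (L|R), equivalve (true|false)`.
#' @param path CSV path.
#' @return data.frame with normalized `side` ("left"/"right") and logical
#'   `equivalve`.
#' @export
read_specimen_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "region", "family", "functional_group",
            "side", "equivalve")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  md$side <- ifelse(toupper(substr(md$side, 1, 1)) == "R", "right", "left")
  md$equivalve <- tolower(as.character(md$equivalve)) %in% c("true", "t", "1", "yes")
  md
}
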