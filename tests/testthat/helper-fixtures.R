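# Shared fixtures and independent oracles, all built in code.

# session-level cache so expensive fixtures are built once
.fix <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fix[[key]])) assign(key, force(expr), envir = .fix)
  .fix[[key]]
}

# closed unit cube mesh (12 triangles), orientation enforced geometrically
# (outward-facing normals), independent of the functions under test
unit_cube_mesh <- function(side = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  v <- sweep(v, 2, origin, `+`)
  quads <- list(c(1, 2, 4, 3), c(5, 6, 8, 7), c(1, 2, 6, 5),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 4, 8, 6))
  ctr <- colMeans(v)
  faces <- do.call(rbind, lapply(quads, function(q) {
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  for (i in seq_len(nrow(faces))) {
    tri <- faces[i, ]
    n <- pracma_cross(v[tri[2], ] - v[tri[1], ], v[tri[3], ] - v[tri[1], ])
    out <- colMeans(v[tri, ]) - ctr
    if (sum(n * out) < 0) faces[i, ] <- tri[c(1, 3, 2)]
  }
  triangle_mesh(v, faces)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# open unit-square patch in the XY plane (two triangles)
square_patch <- function(side = 1) {
  triangle_mesh(rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0), c(0, side, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

# open hemispherical cap of radius r (no base), outward normals
hemisphere_cap <- function(r = 1, n_theta = 40) {
  g <- shellmorph:::cap_grid(n_theta, 4L * n_theta)
  triangle_mesh(g$dirs * r, g$faces)
}

# near-uniform points on a full sphere (Fibonacci lattice): independent of
# the package's samplers
fib_sphere <- function(n, r = 1) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  rad <- sqrt(pmax(1 - z^2, 0))
  cbind(r * rad * cos(ga * i), r * rad * sin(ga * i), r * z)
}

# leave-one-out nearest-neighbour distances, brute force
nn_dists <- function(P) {
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  apply(D, 1, min)
}

# brute-force minimum spanning tree by exhaustive enumeration (n <= 7):
# the independent oracle for the package's Kruskal implementation
brute_mst <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 7)
  D <- as.matrix(dist(X))
  edges <- t(combn(n, 2))
  w <- D[edges]
  best_w <- Inf; best_set <- NULL
  sets <- combn(nrow(edges), n - 1)
  for (k in seq_len(ncol(sets))) {
    sel <- sets[, k]
    # spanning check via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (!ok) next
    tw <- sum(w[sel])
    if (tw < best_w) { best_w <- tw; best_set <- sel }
  }
  list(total = best_w, edge_weights = sort(w[best_set]))
}

# standard processing chain for a synthetic valve
valve_grid <- function(valve, side = "left", quiet_warn = FALSE) {
  sp <- split_at_commissure(valve$mesh, valve$commissure)
  qfun <- if (quiet_warn) suppressWarnings else identity
  q <- quarter_landmarks(valve$commissure, side = side,
                         reference_point = colMeans(valve$mesh$vertices))
  av <- qfun(orient_and_scale_valve(sp$interior, q, side = side))
  build_semilandmark_grid(av)
}

valve_aligned <- function(valve, side = "left", quiet_warn = FALSE) {
  sp <- split_at_commissure(valve$mesh, valve$commissure)
  qfun <- if (quiet_warn) suppressWarnings else identity
  q <- quarter_landmarks(valve$commissure, side = side,
                         reference_point = colMeans(valve$mesh$vertices))
  qfun(orient_and_scale_valve(sp$interior, q, side = side))
}

rot3 <- function(yaw = 0, pitch = 0, roll = 0) {
  Rz <- matrix(c(cos(yaw), -sin(yaw), 0, sin(yaw), cos(yaw), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(pitch), 0, sin(pitch), 0, 1, 0, -sin(pitch), 0, cos(pitch)),
               3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(roll), -sin(roll), 0, sin(roll), cos(roll)),
               3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

transform_valve <- function(valve, R = diag(3), t = c(0, 0, 0)) {
  valve$mesh <- triangle_mesh(sweep(valve$mesh$vertices %*% t(R), 2, t, `+`),
                              valve$mesh$faces)
  valve$commissure <- commissure_curve(
    sweep(valve$commissure$points %*% t(R), 2, t, `+`),
    beak_index = valve$commissure$beak_index)
  valve
}

# write a manifest of synthetic valves (STL + commissure CSV) to a directory
write_valve_set <- function(dir, n = 3, resolution = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    v <- make_helicospiral_valve(W = 2, D = 0.25, a = 1,
                                 b = 1 + 0.15 * i, resolution = resolution,
                                 truth_resolution = resolution)
    mesh_path <- file.path(dir, sprintf("valve%02d.stl", i))
    comm_path <- file.path(dir, sprintf("comm%02d.csv", i))
    write_stl(v$mesh, mesh_path)
    cp <- v$commissure$points
    flag <- integer(nrow(cp)); flag[v$commissure$beak_index] <- 1L
    write.table(cbind(round(cp, 8), flag), comm_path, sep = ",",
                row.names = FALSE, col.names = FALSE)
    data.frame(specimen_id = sprintf("sp%02d", i),
               species = sprintf("Species_%02d", i),
               region = if (i %% 2 == 0) "GM" else "FK",
               family = "Veneridae", functional_group = "MO-UN-SIS-SUS",
               side = "L", equivalve = "true",
               mesh = basename(mesh_path), commissure = basename(comm_path))
  })
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.csv")
  write.csv(man, man_path, row.names = FALSE)
  man_path
}
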