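# Plane-section semilandmarks, flat-sorting and Procrustes superimposition.

test_that("flat-sorting matches the projected-distance oracle, including overhangs", {
  # oracle: explicit projected distances to the anteriormost point, full sort
  oracle_order <- function(P) {
    flat <- P; flat[, 3] <- 0
    ref <- which.max(flat %*% c(1, 1, 0) / sqrt(2))
    order(sqrt(rowSums(sweep(flat, 2, flat[ref, ])^2)))
  }
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(5:20, 1)
    P <- cbind(runif(k), runif(k), rnorm(k))
    fs <- flat_sort_section(P)
    expect_equal(fs$order, oracle_order(P))
    expect_true(all(diff(fs$dist) >= 0))  # monotone projected distances
  }

  # monotone planar arc: flat-sorted order equals the arc-parameter order
  s <- seq(0, 1, length.out = 15)
  arc <- cbind(1 - s, 1 - s^2 * 0.3, 0.2 * sin(s))
  fs <- flat_sort_section(arc)
  expect_equal(fs$order, seq_len(15))

  # recurved flange: monotone in projection, folded in 3D, so a 3D-distance
  # sort inverts neighbours while the flat sort stays stable
  t <- seq(0, 1, length.out = 12)
  flange <- cbind(1 - t, 0.5 - 0.1 * t, c(0, 0.05, 0.3, 0.9, 1.4, 1.6, 1.5,
                                          1.0, 0.5, 0.2, 0.05, 0))
  fs2 <- flat_sort_section(flange)
  expect_equal(fs2$order, seq_len(12))
  ref3 <- which.max(flange %*% c(1, 1, 0))
  d3 <- sqrt(rowSums(sweep(flange, 2, flange[ref3, ])^2))
  expect_false(identical(order(d3), seq_len(12)))  # 3D sort really inverts
})

test_that("plane sections give 101 anterior-anchored points on cross-sections", {
  # axis-aligned open cylinder along x, sectioned mid-length
  n_a <- 48; n_x <- 20
  th <- 2 * pi * (seq_len(n_a) - 1) / n_a
  xs <- seq(0, 2, length.out = n_x)
  V <- do.call(rbind, lapply(xs, function(x) cbind(x, cos(th), sin(th))))
  idx <- function(i, j) (i - 1L) * n_a + ((j - 1L) %% n_a) + 1L
  F <- do.call(rbind, lapply(seq_len(n_x - 1), function(i)
    do.call(rbind, lapply(seq_len(n_a), function(j)
      rbind(c(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1)),
            c(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j)))))))
  cyl <- triangle_mesh(V, F)
  pts <- section_semilandmarks(cyl, section_point = c(1, 0, 0),
                               axis = c(1, 0, 0))
  expect_equal(nrow(pts), 101L)
  expect_equal(pts[, 1], rep(1, 101), tolerance = 1e-9)          # on the plane
  expect_equal(sqrt(pts[, 2]^2 + pts[, 3]^2), rep(1, 101), tolerance = 0.01)
  # first point is the anteriormost candidate
  expect_equal(which.max(pts %*% c(1, 1, 0)), 1L)
  # plane that misses the mesh
  expect_null(section_semilandmarks(cyl, c(10, 0, 0), c(1, 0, 0)))
})

test_that("the semilandmark grid is exactly 100 x 101, deterministic and invariant", {
  v <- cached("helico12", make_helicospiral_valve(resolution = 12))
  g <- cached("helico12_grid", valve_grid(v))
  expect_equal(nrow(g$points), 10100L)
  expect_equal(unname(table(g$section)), rep(101L, 100L), ignore_attr = TRUE)

  # deterministic: identical input -> bit-identical grid
  g2 <- valve_grid(v)
  expect_identical(g$points, g2$points)

  # sections lie on their sampling planes
  av <- valve_aligned(v)
  beak <- av$quarters$beak; vec <- av$quarters$ventral - beak
  ax <- vec / sqrt(sum(vec^2))
  for (s in c(1, 25, 50, 75, 99)) {
    pts <- g$points[g$section == s, , drop = FALSE]
    offs <- sweep(pts, 2, beak + (s / 100) * vec) %*% ax
    expect_lt(max(abs(offs)), 1e-6)
  }

  # within-section projected distances are nondecreasing
  for (s in c(10, 40, 80)) {
    pts <- g$points[g$section == s, , drop = FALSE]
    fs <- flat_sort_section(pts)
    expect_equal(fs$order, seq_len(101))
  }

  # rigid motion of the input valve leaves the grid unchanged
  v2 <- transform_valve(v, R = rot3(-0.9, 0.35, 1.7), t = c(-4, 8, 1))
  g3 <- valve_grid(v2)
  expect_equal(g3$points, g$points, tolerance = 1e-6)
})

test_that("generalized Procrustes alignment is a similarity-invariant fixed point", {
  v <- cached("helico12", make_helicospiral_valve(resolution = 12))
  g <- cached("helico12_grid", valve_grid(v))
  av <- valve_aligned(v)
  base <- g$points

  # three perturbed copies with known small noise
  set.seed(5)
  grids <- lapply(1:3, function(i) base + matrix(rnorm(length(base), sd = 0.002),
                                                 nrow(base)))
  fixed <- lapply(1:3, function(i) shellmorph:::quarters_matrix(av$quarters) +
                    matrix(rnorm(12, sd = 0.002), 4))
  ps <- gpa_align(grids, fixed)

  # two identical configurations superimpose exactly
  ps_id <- gpa_align(list(base, base),
                     list(shellmorph:::quarters_matrix(av$quarters),
                          shellmorph:::quarters_matrix(av$quarters)))
  expect_equal(ps_id$aligned[[1]], ps_id$aligned[[2]], tolerance = 1e-12)

  # similarity transforms of one specimen do not change its aligned output
  R <- rot3(2.2, -0.7, 0.4)
  grids2 <- grids; fixed2 <- fixed
  grids2[[2]] <- sweep(3.1 * grids[[2]] %*% t(R), 2, c(9, -2, 5), `+`)
  fixed2[[2]] <- sweep(3.1 * fixed[[2]] %*% t(R), 2, c(9, -2, 5), `+`)
  ps2 <- gpa_align(grids2, fixed2)
  for (i in 1:3)
    expect_equal(ps2$aligned[[i]], ps$aligned[[i]], tolerance = 1e-8)

  # consensus equals the mean of aligned configurations, and re-running the
  # alignment on its own output is a fixed point
  expect_equal(ps$consensus, Reduce(`+`, ps$fixed_aligned) / 3, tolerance = 1e-12)
  ps3 <- gpa_align(ps$aligned, ps$fixed_aligned)
  for (i in 1:3)
    expect_equal(ps3$aligned[[i]], ps$aligned[[i]], tolerance = 1e-8)

  # degenerate inputs are rejected
  expect_error(gpa_align(grids[1], fixed[1]), "at least 2")
  line <- cbind(1:4, 0, 0)
  expect_error(gpa_align(grids[1:2], list(fixed[[1]], line)), "collinear")
})

test_that("grid export formats round-trip point coordinates", {
  v <- cached("helico12", make_helicospiral_valve(resolution = 12))
  g <- cached("helico12_grid", valve_grid(v))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(list(g), f1, ids = "spec1")
  df <- read.csv(f1, check.names = FALSE)
  expect_equal(nrow(df), 1L)
  expect_equal(ncol(df), 1L + 3L * 10100L)
  expect_equal(as.numeric(df[1, 2:4]), unname(g$points[1, ]), tolerance = 1e-9)

  f2 <- withr::local_tempfile(fileext = ".txt")
  write_landmark_file(g, f2)
  lines <- readLines(f2)
  expect_equal(lines[1], "LM3=10100")
  expect_equal(length(lines), 10101L)
})
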