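# Thickness field, ornamentation summaries and volume/propSV accounting.

planar_grid <- function(n = 40, z = 0, side = 1) {
  g <- expand.grid(x = seq(0, side, length.out = n),
                   y = seq(0, side, length.out = n))
  cbind(g$x, g$y, z)
}

test_that("thickness field recovers constant-thickness slabs and shell gaps", {
  # two parallel planar grids offset by t: all distances ~ t, baseline ~ t
  t0 <- 0.37
  tf <- thickness_field(planar_grid(40, z = t0), planar_grid(40, z = 0))
  expect_equal(unname(range(tf$distances)), c(t0, t0), tolerance = 1e-3)
  expect_equal(tf$modal_baseline, t0, tolerance = 1e-3)

  # concentric spheres radii r, R: distances ~ R - r
  R <- 1; r <- 0.8
  tf2 <- thickness_field(fib_sphere(1500, R), fib_sphere(4000, r))
  expect_lt(abs(mean(tf2$distances) - (R - r)), 0.02 * (R - r))
  expect_lt(max(abs(tf2$distances - (R - r))), 0.05 * (R - r))

  # identical clouds: zero thickness warning, baseline 0
  P <- planar_grid(15)
  expect_warning(tf3 <- thickness_field(P, P), "zero thickness")
  expect_equal(tf3$modal_baseline, 0)
})

test_that("modal baseline resists implanted bumps and scales with the specimen", {
  # slab with one Gaussian bump of height h; mode must stay at t, not t + h
  t0 <- 0.2; h <- 0.08
  g <- planar_grid(80, z = 0)
  top <- planar_grid(80, z = t0)
  d2 <- (top[, 1] - 0.5)^2 + (top[, 2] - 0.5)^2
  top[, 3] <- top[, 3] + h * exp(-d2 / (2 * 0.01))
  tf <- thickness_field(top, g)
  expect_gt(h, diff(tf$bin_edges[1:2]))  # bump clearly exceeds one bin
  expect_lt(abs(tf$modal_baseline - t0), diff(tf$bin_edges[1:2]))

  # rigid motion of both clouds leaves the field unchanged; scaling scales it
  R <- rot3(0.3, 1.2, -0.5); tr <- c(3, -2, 1)
  tfr <- thickness_field(sweep(top %*% t(R), 2, tr, `+`),
                         sweep(g %*% t(R), 2, tr, `+`))
  expect_equal(tfr$distances, tf$distances, tolerance = 1e-10)
  tfs <- thickness_field(3 * top, 3 * g)
  expect_equal(tfs$modal_baseline, 3 * tf$modal_baseline, tolerance = 1e-10)
})

test_that("ornament summaries expose signed heights and ordered quantiles", {
  t0 <- 0.2; h <- 0.08
  g <- planar_grid(80, z = 0)
  top <- planar_grid(80, z = t0)
  d2 <- (top[, 1] - 0.5)^2 + (top[, 2] - 0.5)^2
  top[, 3] <- top[, 3] + h * exp(-d2 / (2 * 0.01))
  os <- ornament_summary(thickness_field(top, g))
  bw <- os$bin_width
  expect_gte(os$q100, os$q99); expect_gte(os$q99, os$q98)
  expect_gte(os$q98, os$q95)
  expect_lt(abs(os$max_height - h), bw)

  # smooth slab: max height below one bin width
  os0 <- ornament_summary(thickness_field(planar_grid(40, z = t0),
                                          planar_grid(40, z = 0)))
  expect_lt(abs(os0$max_height), os0$bin_width)

  # spined shells give right-skewed thickness: mode < median < mean
  # (sampled over the outer cap; the flat rim band of the solid fixture is a
  # construction artifact, not shell surface)
  v <- add_ornament(cached("hemi16", make_hemispherical_valve(resolution = 16)),
                    "spines", amplitude = 0.1, count = 5, width = 0.25)
  sp <- split_at_commissure(v$mesh, v$commissure)
  ext <- poisson_disk_points(sp$exterior, 6000, seed = 1)
  cap_only <- ext$points[ext$points[, 3] > 0.02, , drop = FALSE]
  tf <- thickness_field(cap_only,
                        poisson_disk_points(sp$interior, 6000, seed = 2))
  expect_lt(tf$modal_baseline, median(tf$distances))
  expect_lt(median(tf$distances), mean(tf$distances))
  expect_error(ornament_summary(thickness_field(planar_grid(10), planar_grid(10, z = 1)),
                                quantile = 0.5), "quantile")
})

test_that("volume summary follows the doubling and summation contracts", {
  # meshes engineered to exact volumes: SV from closed cubes, IV from open
  # boxes whose commissure-capped cone volume equals the full cube volume
  open_box <- function(side) {
    cube <- unit_cube_mesh(side = side)
    top <- apply(cube$faces, 1, function(tri)
      all(cube$vertices[tri, 3] == side))
    shellmorph:::subset_mesh_faces(cube, which(!top))
  }
  valve1 <- list(whole = unit_cube_mesh(side = 1), interior = open_box(3^(1 / 3)),
                 cloud = NULL)
  vs <- volume_summary(list(valve1), equivalve = TRUE)
  expect_equal(vs$TSV, 2, tolerance = 1e-10)
  expect_equal(vs$TIV, 6, tolerance = 1e-10)
  expect_equal(vs$propSV, 0.25, tolerance = 1e-10)

  valve2 <- list(whole = unit_cube_mesh(side = 2^(1 / 3)),
                 interior = open_box(4^(1 / 3)), cloud = NULL)
  vs2 <- volume_summary(list(valve1, valve2), equivalve = FALSE)
  expect_equal(vs2$TSV, 3, tolerance = 1e-10)
  expect_equal(vs2$TIV, 7, tolerance = 1e-10)
  expect_equal(vs2$propSV, 0.3, tolerance = 1e-10)

  # arity contract
  expect_error(volume_summary(list(valve1, valve2), equivalve = TRUE), "exactly 1")
  expect_error(volume_summary(list(valve1), equivalve = FALSE), "exactly 2")
})

test_that("equivalve doubling equals inequivalve processing of the mirror pair", {
  v <- cached("hemi24", make_hemispherical_valve(R = 1, t = 0.2, resolution = 24))
  vr <- mirror_valve(v)
  mk <- function(valve, seed) {
    sp <- split_at_commissure(valve$mesh, valve$commissure)
    list(whole = valve$mesh, interior = sp$interior,
         cloud = poisson_disk_points(valve$mesh, 2000, seed = seed))
  }
  a <- mk(v, 1)
  vs_eq <- volume_summary(list(a), equivalve = TRUE)
  vs_in <- volume_summary(list(a, mk(vr, 1)), equivalve = FALSE)
  expect_equal(vs_in$TSV, vs_eq$TSV, tolerance = 1e-9)
  expect_equal(vs_in$TIV, vs_eq$TIV, tolerance = 1e-9)
  expect_equal(vs_in$propSV, vs_eq$propSV, tolerance = 1e-9)
  # mirrored Poisson cloud has the mirrored centroid size only through
  # sampling noise; compare on the analytic route instead
  expect_equal(vs_in$body_centroid_size, vs_eq$body_centroid_size,
               tolerance = 0.02 * vs_eq$body_centroid_size)
})

test_that("propSV is invariant under isotropic scaling of the specimen", {
  v <- cached("hemi16", make_hemispherical_valve(resolution = 16))
  sp <- split_at_commissure(v$mesh, v$commissure)
  base <- volume_summary(list(list(whole = v$mesh, interior = sp$interior,
                                   cloud = NULL)), equivalve = TRUE)
  for (s in c(0.2, 5)) {
    ms <- triangle_mesh(s * v$mesh$vertices, v$mesh$faces)
    is_ <- triangle_mesh(s * sp$interior$vertices, sp$interior$faces)
    vs <- volume_summary(list(list(whole = ms, interior = is_, cloud = NULL)),
                         equivalve = TRUE)
    expect_equal(vs$propSV, base$propSV, tolerance = 1e-10)
    expect_equal(vs$TSV, s^3 * base$TSV, tolerance = 1e-8 * s^3 * base$TSV)
  }
})
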