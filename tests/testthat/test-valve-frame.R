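# Commissure quartering, interior/exterior splitting and frame alignment.

circle_curve <- function(n = 60, r = 1, jitter = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  commissure_curve(cbind(r * cos(th), r * sin(th), jitter * sin(3 * th)),
                   beak_index = 1L)
}

test_that("quarter landmarks sit at clockwise quarter arcs regardless of input traversal", {
  cc <- circle_curve(n = 720)
  q <- quarter_landmarks(cc)
  # clockwise from (1,0,0) viewed from +z: quarters at 0, -90, -180, -270 deg
  expect_equal(q$beak, c(1, 0, 0), tolerance = 1e-6)
  expect_equal(q$anterior, c(0, -1, 0), tolerance = 1e-4)
  expect_equal(q$ventral, c(-1, 0, 0), tolerance = 1e-4)
  expect_equal(q$posterior, c(0, 1, 0), tolerance = 1e-4)

  # reversed traversal order gives identical quarters
  p <- cc$points
  rev_curve <- commissure_curve(p[c(1, nrow(p):2), ], beak_index = 1L)
  q2 <- quarter_landmarks(rev_curve)
  for (f in c("beak", "anterior", "ventral", "posterior"))
    expect_equal(q2[[f]], q[[f]], tolerance = 1e-9)

  # starting-index invariance: rotate the stored point order
  shift <- 100
  p3 <- p[c((shift + 1):nrow(p), 1:shift), ]
  q3 <- quarter_landmarks(commissure_curve(p3, beak_index = nrow(p) - shift + 1L))
  for (f in c("beak", "anterior", "ventral", "posterior"))
    expect_equal(q3[[f]], q[[f]], tolerance = 1e-9)

  # 75-point resample of a circle radius r: centroid size = r sqrt(75)
  for (r in c(0.5, 2, 7)) {
    qr <- quarter_landmarks(circle_curve(720, r = r))
    expect_equal(qr$centroid_size, r * sqrt(75), tolerance = 0.005 * r * sqrt(75))
  }
})

test_that("open commissures beyond the gap tolerance are rejected", {
  th <- seq(0, 1.2 * pi, length.out = 50)  # large endpoint gap
  expect_error(commissure_curve(cbind(cos(th), sin(th), 0)), "gap")
  # small gap (implied closure) is accepted
  th2 <- seq(0, 2 * pi * 0.99, length.out = 100)
  expect_s3_class(commissure_curve(cbind(cos(th2), sin(th2), 0)),
                  "commissure_curve")
})

test_that("commissure split partitions faces into interior and exterior surfaces", {
  v <- cached("hemi24", make_hemispherical_valve(R = 1, t = 0.2, resolution = 24))
  sp <- split_at_commissure(v$mesh, v$commissure)
  # every face on exactly one side
  expect_equal(nrow(sp$interior$faces) + nrow(sp$exterior$faces),
               nrow(v$mesh$faces))
  # interior is the inner cap: all vertices at the inner radius
  ri <- sqrt(rowSums(sp$interior$vertices^2))
  expect_equal(range(ri), c(0.8, 0.8), tolerance = 1e-9)
  # exterior contains the outer cap and the rim annulus
  re <- sqrt(rowSums(sp$exterior$vertices^2))
  expect_equal(max(re), 1, tolerance = 1e-9)
  # split then re-merge: vertex set equals the original
  all_v <- rbind(sp$interior$vertices, sp$exterior$vertices)
  expect_equal(sort(unique(round(as.vector(all_v), 9))),
               sort(unique(round(as.vector(v$mesh$vertices), 9))))

  # commissure dilated beyond the valve rim -> validation error
  off <- commissure_curve(v$commissure$points * 1.5,
                          beak_index = v$commissure$beak_index)
  expect_error(split_at_commissure(v$mesh, off), "gap|surface")
})

test_that("frame alignment recovers known rotations and is rigid-motion invariant", {
  # quarters already at targets: identity, residual 0
  targets <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  q0 <- structure(list(beak = targets[1, ], anterior = targets[2, ],
                       ventral = targets[3, ], posterior = targets[4, ],
                       resampled = targets, centroid_size = 1),
                  class = "quarter_landmarks")
  mesh <- triangle_mesh(rbind(targets, c(0.5, 0.5, -0.3)),
                        rbind(c(1, 2, 5), c(3, 4, 5)))
  av <- orient_and_scale_valve(mesh, q0, side = "left")
  expect_lt(av$residual, 1e-12)
  expect_equal(av$mesh$vertices, mesh$vertices, tolerance = 1e-12)
  expect_false(av$mirrored)

  # a known rotation applied to quarters + mesh is inverted exactly
  R <- rot3(0.8, -0.4, 1.9); tr <- c(2, -1, 4)
  qr <- q0
  qm <- sweep(targets %*% t(R), 2, tr, `+`)
  qr$beak <- qm[1, ]; qr$anterior <- qm[2, ]; qr$ventral <- qm[3, ]
  qr$posterior <- qm[4, ]
  qr$resampled <- sweep(q0$resampled %*% t(R), 2, tr, `+`)
  mesh_r <- triangle_mesh(sweep(mesh$vertices %*% t(R), 2, tr, `+`), mesh$faces)
  av_r <- orient_and_scale_valve(mesh_r, qr, side = "left")
  expect_lt(av_r$residual, 1e-9)
  expect_equal(av_r$mesh$vertices, mesh$vertices, tolerance = 1e-9)

  # collinear quarters are rejected
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  qbad <- structure(list(beak = line[1, ], anterior = line[2, ],
                         ventral = line[3, ], posterior = line[4, ],
                         resampled = line, centroid_size = 1),
                    class = "quarter_landmarks")
  expect_error(orient_and_scale_valve(mesh, qbad), "collinear")

  # full pipeline invariance on a generic valve under an arbitrary rigid motion
  v <- cached("helico12", make_helicospiral_valve(resolution = 12))
  a1 <- valve_aligned(v)
  v2 <- transform_valve(v, R = rot3(1.1, 0.6, -2.0), t = c(5, -3, 2))
  a2 <- valve_aligned(v2)
  expect_equal(a1$mesh$vertices, a2$mesh$vertices, tolerance = 1e-6)
  expect_equal(a1$residual, a2$residual, tolerance = 1e-9)
})

test_that("right valves mirror onto the aligned left valve of a mirror pair", {
  v <- cached("helico12", make_helicospiral_valve(resolution = 12))
  vr <- mirror_valve(v)
  al <- valve_aligned(v, side = "left")
  ar <- valve_aligned(vr, side = "right")
  expect_true(ar$mirrored)
  expect_false(al$mirrored)
  expect_equal(ar$mesh$vertices, al$mesh$vertices, tolerance = 1e-9)
  g1 <- build_semilandmark_grid(al)
  g2 <- build_semilandmark_grid(ar)
  expect_equal(g1$points, g2$points, tolerance = 1e-9)
})

test_that("commissure CSV round-trips points and the beak flag", {
  cc <- circle_curve(50)
  f <- withr::local_tempfile(fileext = ".csv")
  flag <- integer(50); flag[7] <- 1L
  write.table(cbind(cc$points, flag), f, sep = ",", row.names = FALSE,
              col.names = FALSE)
  back <- read_commissure_csv(f)
  expect_equal(back$points, cc$points, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$beak_index, 7L)
})
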