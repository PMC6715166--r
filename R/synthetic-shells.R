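# Synthetic valves and faunas: parametric shell meshes with known volumes and
# implanted ornament, and simulated multi-group trait/score tables, so every
# pipeline stage can be exercised without scan data.

# triangulated spherical-cap grid (theta in [0, pi/2] from the +z pole)
cap_grid <- function(n_theta, n_phi) {
  n_theta <- as.integer(n_theta); n_phi <- as.integer(n_phi)
  theta <- seq_len(n_theta) * (pi / 2) / n_theta
  phi <- (seq_len(n_phi) - 1L) * 2 * pi / n_phi
  grid <- expand.grid(phi = phi, theta = theta)  # phi fastest, matches indexing
  dirs <- rbind(c(0, 0, 1),
                cbind(sin(grid$theta) * cos(grid$phi),
                      sin(grid$theta) * sin(grid$phi),
                      cos(grid$theta)))
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- matrix(0L, nrow = n_phi + 2L * n_phi * (n_theta - 1L), ncol = 3L)
  r <- 1L
  for (j in seq_len(n_phi)) {  # pole fan, CCW from above = outward
    faces[r, ] <- c(1L, idx(1L, j), idx(1L, j + 1L)); r <- r + 1L
  }
  if (n_theta > 1L) for (i in seq_len(n_theta - 1L)) for (j in seq_len(n_phi)) {
    a <- idx(i, j); b <- idx(i, j + 1L); c <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
    faces[r, ] <- c(a, c, b); r <- r + 1L   # outward normals
    faces[r, ] <- c(a, d, c); r <- r + 1L
  }
  rim <- vapply(seq_len(n_phi), function(j) idx(n_theta, j), 0L)
  list(dirs = dirs, faces = faces, rim = rim,
       theta = c(0, grid$theta), phi = c(0, grid$phi))
}

#' Synthetic hemispherical valve with known volumes
#'
#' A closed shell solid between concentric hemispheres of radii `R` (outer)
#' and `R - t` (inner), closed by a flat equatorial annulus, with the
#' commissure along the inner equatorial circle. Analytic truth values:
#' shell volume `(2/3) pi (R^3 - (R-t)^3)` and internal volume
#' `(2/3) pi (R-t)^3`.
#'
#' @param R outer radius (mm).
#' @param t shell thickness (mm), `0 < t < R`.
#' @param resolution number of latitude rings per cap (default 24; faces
#'   scale as `~4 resolution^2` per cap).
#' @return an object of class `synthetic_valve`: `mesh` (closed
#'   `triangle_mesh`), `commissure` (`commissure_curve`), `truth` (list:
#'   `SV`, `IV`, `propSV`, `ornament`, `side`, `equivalve`), plus vertex
#'   index bookkeeping for ornament implanting.
#' @export
make_hemispherical_valve <- function(R = 1, t = 0.2, resolution = 24L) {
  if (!(t > 0 && t < R)) stop("thickness must satisfy 0 < t < R")
  n_theta <- as.integer(resolution); n_phi <- 4L * n_theta
  g <- cap_grid(n_theta, n_phi)
  r <- R - t
  n_cap <- nrow(g$dirs)
  outerV <- g$dirs * R
  innerV <- g$dirs * r
  V <- rbind(outerV, innerV)
  outerF <- g$faces
  innerF <- g$faces[, c(1, 3, 2)] + n_cap       # reversed: normals into cavity
  orim <- g$rim; irim <- g$rim + n_cap
  ann <- matrix(0L, nrow = 2L * n_phi, ncol = 3L)
  for (j in seq_len(n_phi)) {
    a <- orim[j]; b <- orim[j %% n_phi + 1L]
    c2 <- irim[j %% n_phi + 1L]; d <- irim[j]
    ann[2L * j - 1L, ] <- c(a, c2, b)           # wound for -z normals
    ann[2L * j, ] <- c(a, d, c2)
  }
  mesh <- triangle_mesh(V, rbind(outerF, innerF, ann))
  commissure <- commissure_curve(V[irim, , drop = FALSE], beak_index = 1L)
  truth <- list(SV = 2 / 3 * pi * (R^3 - r^3), IV = 2 / 3 * pi * r^3,
                propSV = (R^3 - r^3) / R^3, ornament = 0,
                side = "left", equivalve = TRUE)
  structure(list(mesh = mesh, commissure = commissure, truth = truth,
                 exterior_idx = setdiff(seq_len(n_cap), integer(0)),
                 rim_idx = orim, R = R, t = t),
            class = "synthetic_valve")
}

#' @export
print.synthetic_valve <- function(x, ...) {
  cat(sprintf("synthetic_valve: %d faces; truth SV %.4f, IV %.4f, propSV %.4f, ornament %.3f\n",
              nrow(x$mesh$faces), x$truth$SV, x$truth$IV, x$truth$propSV,
              x$truth$ornament))
  invisible(x)
}

helico_surface <- function(W, D, a, b, height, R0, asym, n_theta, n_phi) {
  g <- cap_grid(n_theta, n_phi)
  th <- g$theta; ph <- g$phi
  frac <- th / (pi / 2)
  rho <- R0 * W^(frac - 1)                       # expands toward the aperture
  # aperture asymmetry breaks the two mirror axes of a plain ellipse, as in
  # real valves; a perfectly bi-symmetric commissure leaves the four-landmark
  # alignment roll-degenerate
  mod <- 1 + asym * cos(ph - pi / 5)
  x <- rho * sin(th) * cos(ph) * a * mod + D * R0 * (1 - frac)^2
  y <- rho * sin(th) * sin(ph) * b * mod
  z <- rho * cos(th) * height
  list(V = cbind(x, y, z), faces = g$faces, rim = g$rim)
}

#' Synthetic helicospiral (Raup-style) valve
#'
#' A cap-like valve swept by scaling and translating a generating ellipse:
#' the radius expands geometrically with the whorl-expansion rate `W` from
#' the beak toward the aperture, the beak is offset by the translation rate
#' `D`, and the aperture ellipse has semi-axes `a` and `b` (elongation).
#' The inner surface is the outer surface shrunk radially by the shell
#' thickness and the two are closed by a rim band; the commissure follows
#' the inner rim. Truth volumes are measured on a reference mesh of roughly
#' 10x the face count (no closed form exists for general sweeps).
#'
#' @param W whorl expansion rate (> 1).
#' @param D beak translation rate (dimensionless offset of the apex).
#' @param a,b aperture semi-axes (mm); `b/a` is the elongation.
#' @param height dorsoventral depth scale of the valve (mm-scaled factor).
#' @param thickness radial shell thickness (mm).
#' @param asym aperture asymmetry amplitude (dimensionless, default 0.1): a
#'   small azimuthal modulation of the aperture that removes the two mirror
#'   axes of a plain ellipse. Real commissures are asymmetric; a perfectly
#'   bi-symmetric one leaves the four-landmark rigid fit roll-degenerate.
#' @param resolution latitude rings, default 20.
#' @param truth_resolution rings for the reference ("truth") mesh, default
#'   `3 * resolution` (about 10x the faces).
#' @return a `synthetic_valve`.
#' @export
make_helicospiral_valve <- function(W = 2, D = 0.25, a = 1, b = 1.2,
                                    height = 0.9, thickness = 0.1,
                                    asym = 0.1, resolution = 20L,
                                    truth_resolution = 3L * resolution) {
  if (!(W > 1)) stop("whorl expansion rate W must exceed 1")
  R0 <- max(a, b)
  if (!(thickness > 0 && thickness < 0.5 * min(a, b) * R0 / W))
    stop("thickness too large for this coiling geometry (self-intersection)")
  build <- function(n_theta) {
    n_phi <- 4L * n_theta
    s <- helico_surface(W, D, a, b, height, R0, asym, n_theta, n_phi)
    P <- s$V
    rad <- sqrt(rowSums(P^2))
    inner <- P * (1 - thickness / rad)
    n_cap <- nrow(P)
    V <- rbind(P, inner)
    outerF <- s$faces
    innerF <- s$faces[, c(1, 3, 2)] + n_cap
    orim <- s$rim; irim <- s$rim + n_cap
    ann <- matrix(0L, nrow = 2L * n_phi, ncol = 3L)
    for (j in seq_len(n_phi)) {
      aa <- orim[j]; bb <- orim[j %% n_phi + 1L]
      cc <- irim[j %% n_phi + 1L]; dd <- irim[j]
      ann[2L * j - 1L, ] <- c(aa, cc, bb)
      ann[2L * j, ] <- c(aa, dd, cc)
    }
    list(mesh = triangle_mesh(V, rbind(outerF, innerF, ann)),
         inner = inner, irim = irim, orim = orim, n_cap = n_cap)
  }
  m <- build(as.integer(resolution))
  ref <- build(as.integer(truth_resolution))
  SVt <- cone_volume(ref$mesh, check_winding = FALSE)
  # interior reference surface: inner cap only
  nthr <- as.integer(truth_resolution); nphr <- 4L * nthr
  inner_faces_ref <- cap_grid(nthr, nphr)$faces[, c(1, 3, 2)]
  int_ref <- triangle_mesh(ref$inner, inner_faces_ref)
  bidx <- boundary_vertices(int_ref)
  IVt <- abs(cone_volume(int_ref, apex = colMeans(int_ref$vertices[bidx, , drop = FALSE]),
                         check_winding = FALSE))
  apex_pt <- m$mesh$vertices[1, ]
  rim_pts <- m$mesh$vertices[m$irim, , drop = FALSE]
  beak_j <- which.min((rim_pts[, 1] - apex_pt[1])^2 + (rim_pts[, 2] - apex_pt[2])^2)
  commissure <- commissure_curve(rim_pts, beak_index = beak_j)
  truth <- list(SV = SVt, IV = IVt, propSV = SVt / (SVt + IVt), ornament = 0,
                side = "left", equivalve = TRUE)
  structure(list(mesh = m$mesh, commissure = commissure, truth = truth,
                 exterior_idx = seq_len(m$n_cap), rim_idx = m$orim,
                 R = R0, t = thickness,
                 params = list(W = W, D = D, a = a, b = b, height = height,
                               thickness = thickness, asym = asym,
                               resolution = resolution)),
            class = "synthetic_valve")
}

#' Implant ornament (spines or ribs) on a synthetic valve
#'
#' Displaces exterior-surface vertices outward along the radial direction:
#' Gaussian bumps ("spines") around evenly spread centers, or sinusoidal
#' radial "ribs". The displacement field is normalized so its maximum equals
#' `amplitude` exactly at one mesh vertex, and tapers to zero at the valve
#' rim; interior surface and commissure are untouched. The truth ornament
#' height is set to `amplitude` and the truth shell volume is re-measured on
#' the modified mesh.
#'
#' @param valve a `synthetic_valve`.
#' @param kind `"spines"` or `"ribs"`.
#' @param amplitude maximum ornament height (mm); 0 leaves the mesh
#'   unchanged.
#' @param count number of spines or ribs, default 5.
#' @param width angular Gaussian width of a spine (radians), default 0.3.
#' @return the modified `synthetic_valve`.
#' @export
add_ornament <- function(valve, kind = c("spines", "ribs"), amplitude,
                         count = 5L, width = 0.3) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (amplitude == 0) return(valve)
  if (amplitude > valve$R / 2)
    stop("amplitude exceeds half the valve scale")
  V <- valve$mesh$vertices
  ext <- setdiff(valve$exterior_idx, valve$rim_idx)
  P <- V[ext, , drop = FALSE]
  rad <- sqrt(rowSums(P^2))
  u <- P / rad
  coslat <- pmax(P[, 3] / rad, 0)                 # 1 at the apex, 0 at the rim
  taper <- coslat^0.5
  phiv <- atan2(P[, 2], P[, 1])
  if (kind == "spines") {
    centers_phi <- 2 * pi * (seq_len(count) - 0.5) / count
    ctheta <- pi / 4                               # spine band at mid-latitude
    cdirs <- cbind(sin(ctheta) * cos(centers_phi),
                   sin(ctheta) * sin(centers_phi),
                   rep(cos(ctheta), count))
    ang <- acos(pmin(pmax(u %*% t(cdirs), -1), 1))  # angular distance to centers
    g <- exp(-(apply(ang, 1, min) / width)^2 / 2)
    field <- g * taper
  } else {
    field <- (0.5 + 0.5 * cos(count * phiv))^2 * taper
  }
  if (max(field) <= 0) stop("ornament field vanished on the exterior surface")
  disp <- amplitude * field / max(field)
  V[ext, ] <- P + u * disp
  valve$mesh <- triangle_mesh(V, valve$mesh$faces)
  valve$truth$ornament <- amplitude
  valve$truth$SV <- cone_volume(valve$mesh, check_winding = FALSE)
  valve$truth$propSV <- valve$truth$SV / (valve$truth$SV + valve$truth$IV)
  valve
}

#' Mirror a synthetic valve into its right-valve counterpart
#'
#' Reflects the mesh and commissure across the XZ plane and flips face
#' winding, producing the opposite valve of an equivalve pair.
#' @param valve a `synthetic_valve`.
#' @return the mirrored `synthetic_valve` with `truth$side = "right"`.
#' @export
mirror_valve <- function(valve) {
  V <- valve$mesh$vertices
  V[, 2] <- -V[, 2]
  valve$mesh <- triangle_mesh(V, valve$mesh$faces[, c(1, 3, 2), drop = FALSE])
  cp <- valve$commissure$points
  cp[, 2] <- -cp[, 2]
  valve$commissure <- commissure_curve(cp, beak_index = valve$commissure$beak_index)
  valve$truth$side <- "right"
  valve
}

# ---------------------------------------------------------------------------
# Simulated faunas
# ---------------------------------------------------------------------------

default_families <- c("Veneridae", "Tellinidae", "Mytilidae", "Pectinidae",
                      "Chamidae", "Cardiidae", "Spondylidae", "Mactridae",
                      "Astartidae", "Nuculidae", "Arcidae", "Corbulidae",
                      "Thraciidae", "Ostreidae")

default_fgroups <- c("MO-UN-SIS-SUS", "MO-UN-DIS-SUS", "IM-BY-EP-SUS",
                     "IM-CE-EP-SUS", "MO-UN-INA-SBD", "SW-UN-EP-SUS",
                     "MO-BY-SMI-SUS", "MO-UN-NE-MDS")

#' Default configuration for simulated faunas
#'
#' Regional species pools mirroring the study system: a species-rich
#' tropical fauna (FK, 355 species) and a smaller boreal fauna (GM, 90
#' species); 23 shape-score axes with a decaying variance spectrum whose
#' first two axes carry roughly a third and a fifth of the variance;
#' lognormal centroid size, gamma (exponential-tailed) ornament, and
#' logit-normal shell proportion centered near 0.28 so most species fall in
#' the 20-40% band within an overall range of roughly 6-80%.
#'
#' @param n_species named vector of species counts per region.
#' @param n_axes number of score axes.
#' @param score_var total score variance per region (relative).
#' @param score_shift optional per-region mean shift along axis 1.
#' @param ornament_scale per-region scale of the gamma ornament
#'   distribution.
#' @param ornament_heavy_tail region name whose ornament gets an extra
#'   lognormal heavy upper tail, or `NULL` (default). The tail is carried by
#'   the species of `ornament_tail_families` in that region, emulating the
#'   concentration of strong defensive ornament (spines) in particular
#'   cemented/epifaunal clades rather than across the whole fauna.
#' @param ornament_tail_families families carrying the heavy tail.
#' @return a configuration list for [simulate_fauna()].
#' @export
fauna_config <- function(n_species = c(FK = 355L, GM = 90L),
                         n_axes = 23L,
                         score_var = c(FK = 1, GM = 1),
                         score_shift = c(FK = 0, GM = 0),
                         ornament_scale = c(FK = 1, GM = 1),
                         ornament_heavy_tail = NULL,
                         ornament_tail_families = c("Chamidae", "Spondylidae")) {
  regions <- names(n_species)
  if (is.null(regions) || any(!nzchar(regions)))
    stop("n_species must be a named vector of regions")
  spectrum <- c(0.33, 0.18, 0.49 * 0.8^(seq_len(n_axes - 2L) - 1L))
  spectrum <- spectrum / sum(spectrum)
  list(regions = regions, n_species = n_species, n_axes = n_axes,
       spectrum = spectrum, score_var = score_var, score_shift = score_shift,
       families = default_families, fgroups = default_fgroups,
       size_meanlog = log(30), size_sdlog = 0.8,
       ornament_shape = 1.2, ornament_scale = ornament_scale,
       ornament_heavy_tail = ornament_heavy_tail,
       ornament_tail_families = ornament_tail_families,
       propsv_logit_mean = stats::qlogis(0.28), propsv_logit_sd = 0.55)
}

#' Simulate a two-region fauna of species-level scores and traits
#'
#' Species-level shape scores are multivariate normal per region (diagonal
#' covariance along the configured spectrum), and the three non-shape traits
#' are drawn from a lognormal (centroid size), a gamma with optional
#' lognormal heavy upper tail (ornament), and a logit-normal (shell
#' proportion). Family and functional-group labels are sampled with
#' geometrically decaying richness, emulating the dominance of a few
#' species-rich clades. Fully reproducible from the seed; the configuration
#' is stored with the result.
#'
#' @param config a list from [fauna_config()].
#' @param seed RNG seed, default 0.
#' @return an object of class `synthetic_fauna`: `traits` (data.frame with
#'   `species`, `region`, `family`, `functional_group`, `centroid_size`,
#'   `max_ornament`, `propSV`), `scores` (species x axes matrix), `config`,
#'   `seed`.
#' @export
simulate_fauna <- function(config = fauna_config(), seed = 0L) {
  need <- c("regions", "n_species", "n_axes", "spectrum", "score_var",
            "score_shift", "families", "fgroups", "size_meanlog",
            "size_sdlog", "ornament_shape", "ornament_scale",
            "propsv_logit_mean", "propsv_logit_sd")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing field(s): ", paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  rows <- list(); score_rows <- list()
  fam_w <- 0.6^(seq_along(config$families) - 1L)
  fg_w <- 0.6^(seq_along(config$fgroups) - 1L)
  for (rg in config$regions) {
    n <- config$n_species[[rg]]
    sdv <- sqrt(config$spectrum * config$score_var[[rg]])
    S <- vapply(sdv, function(s) stats::rnorm(n, 0, s), numeric(n))
    if (n == 1L) S <- matrix(S, nrow = 1L)
    S[, 1] <- S[, 1] + config$score_shift[[rg]]
    fam <- sample(config$families, n, replace = TRUE, prob = fam_w)
    orn <- stats::rgamma(n, shape = config$ornament_shape,
                         scale = config$ornament_scale[[rg]])
    if (!is.null(config$ornament_heavy_tail) &&
        rg == config$ornament_heavy_tail) {
      # strong defensive ornament is clade-linked, not fauna-wide
      heavy <- fam %in% (config$ornament_tail_families %||% character(0))
      orn[heavy] <- orn[heavy] + stats::rlnorm(sum(heavy), meanlog = 1.4, sdlog = 0.6)
    }
    rows[[rg]] <- data.frame(
      species = sprintf("%s_sp%03d", rg, seq_len(n)),
      region = rg,
      family = fam,
      functional_group = sample(config$fgroups, n, replace = TRUE, prob = fg_w),
      centroid_size = stats::rlnorm(n, config$size_meanlog, config$size_sdlog),
      max_ornament = orn,
      propSV = stats::plogis(stats::rnorm(n, config$propsv_logit_mean,
                                          config$propsv_logit_sd)))
    score_rows[[rg]] <- S
  }
  traits <- do.call(rbind, rows)
  rownames(traits) <- NULL
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- traits$species
  colnames(scores) <- paste0("PC", seq_len(config$n_axes))
  structure(list(traits = traits, scores = scores, config = config,
                 seed = as.integer(seed)),
            class = "synthetic_fauna")
}

#' @export
print.synthetic_fauna <- function(x, ...) {
  tab <- table(x$traits$region)
  cat(sprintf("synthetic_fauna: %s species; %d score axes (seed %d)\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              ncol(x$scores), x$seed))
  invisible(x)
}
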