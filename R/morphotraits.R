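# Non-shape traits: shell-thickness field -> ornamentation height, shell and
# internal volumes -> shell proportion (propSV), and body centroid size.

#' Shell-thickness field between exterior and interior point clouds
#'
#' For each point of the exterior cloud, the minimum Euclidean distance to
#' the interior cloud (exact nearest neighbour, so results are
#' deterministic). The distances are binned into 100 equal-width intervals;
#' the mean of the most populated (modal) bin is the baseline thickness of
#' the hypothetically smooth shell. Ties for the modal bin are broken toward
#' the smaller-thickness bin.
#'
#' @param exterior,interior `point_cloud` objects or `n x 3` matrices
#'   (100,000 points each in the standard protocol).
#' @param n_bins number of histogram bins, default 100.
#' @return an object of class `thickness_field`: `distances`, `bin_edges`,
#'   `bin_counts`, `modal_bin`, `modal_baseline` (mm).
#' @export
thickness_field <- function(exterior, interior, n_bins = 100L) {
  E <- as_points3(exterior); I <- as_points3(interior)
  if (nrow(E) == 0L || nrow(I) == 0L) stop("point clouds must be non-empty")
  d <- cpp_nn_min_dist(E, I)
  rng <- range(d)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    if (rng[2] < 1e-12)
      warning("exterior and interior clouds coincide: zero thickness everywhere")
    edges <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n_bins + 1L)
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  modal <- which.max(counts)  # which.max takes the first (smallest) on ties
  baseline <- mean(d[bin == modal])
  structure(list(distances = d, bin_edges = edges, bin_counts = counts,
                 modal_bin = modal, modal_baseline = baseline),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  cat(sprintf("thickness_field: %d distances, modal baseline %.4f (bin %d of %d)\n",
              length(x$distances), x$modal_baseline, x$modal_bin,
              length(x$bin_counts)))
  invisible(x)
}

#' Ornamentation summary from a thickness field
#'
#' Ornament heights are the signed differences between each thickness
#' measurement and the modal baseline (the hypothetically smooth shell):
#' heights are not floored at zero. The retained "maximum ornamentation
#' height" is, by default, the absolute maximum; the 99th, 98th or 95th
#' quantile are available for robustness, and all four are reported.
#'
#' @param field a `thickness_field`.
#' @param quantile which summary to expose as `max_height`: 1.0 (absolute
#'   maximum, default), 0.99, 0.98 or 0.95.
#' @return an object of class `ornament_summary`: `heights`, `max_height`,
#'   `q99`, `q98`, `q95`, `bin_width`, `baseline`.
#' @export
ornament_summary <- function(field, quantile = 1.0) {
  stopifnot(inherits(field, "thickness_field"))
  if (!quantile %in% c(1.0, 0.99, 0.98, 0.95))
    stop("quantile must be one of 1.0, 0.99, 0.98, 0.95")
  h <- field$distances - field$modal_baseline
  qs <- stats::quantile(h, c(1, 0.99, 0.98, 0.95), names = FALSE, type = 7)
  sel <- qs[match(quantile, c(1, 0.99, 0.98, 0.95))]
  structure(list(heights = h, max_height = sel,
                 q100 = qs[1], q99 = qs[2], q98 = qs[3], q95 = qs[4],
                 bin_width = diff(field$bin_edges[1:2]),
                 baseline = field$modal_baseline),
            class = "ornament_summary")
}

#' @export
print.ornament_summary <- function(x, ...) {
  cat(sprintf(paste0("ornament_summary: baseline %.4f, max height %.4f ",
                     "(q99 %.4f, q98 %.4f, q95 %.4f)\n"),
              x$baseline, x$q100, x$q99, x$q98, x$q95))
  invisible(x)
}

#' Shell and internal volumes, shell proportion and body size of a specimen
#'
#' Per valve, the shell volume SV is the signed-tetrahedra volume of the
#' whole (closed) valve surface, and the internal volume IV is the
#' signed-tetrahedra volume of the open interior surface with the apex at
#' the centroid of its boundary loop (the commissure), which caps the
#' commissure opening with a near-planar fan. For equivalve specimens
#' (one valve supplied) SV, IV and the per-valve centroid size are doubled;
#' for inequivalve specimens (two valves) they are summed. Shell proportion
#' propSV = TSV / (TSV + TIV).
#'
#' @param valves a list of one (equivalve) or two (inequivalve) valves; each
#'   valve is a list with elements `whole` (closed `triangle_mesh`),
#'   `interior` (open `triangle_mesh`) and `cloud` (`point_cloud` on the
#'   whole surface, used for body centroid size).
#' @param equivalve logical flag.
#' @param iv_apex `"boundary"` (default: centroid of the interior surface's
#'   boundary loop) or `"surface"` (centroid of the interior surface's
#'   vertices; underestimates IV for deep valves).
#' @return an object of class `volume_summary`: `TSV`, `TIV`, `propSV`,
#'   `body_centroid_size`, `equivalve`, plus per-valve `SV`, `IV`.
#' @export
volume_summary <- function(valves, equivalve, iv_apex = c("boundary", "surface")) {
  iv_apex <- match.arg(iv_apex)
  if (equivalve && length(valves) != 1L)
    stop("equivalve specimens take exactly 1 valve")
  if (!equivalve && length(valves) != 2L)
    stop("inequivalve specimens take exactly 2 valves")
  SV <- IV <- CS <- numeric(length(valves))
  for (i in seq_along(valves)) {
    v <- valves[[i]]
    SV[i] <- cone_volume(v$whole)
    apex <- if (iv_apex == "boundary") {
      bidx <- boundary_vertices(v$interior)
      if (length(bidx) == 0L) colMeans(v$interior$vertices) else
        colMeans(v$interior$vertices[bidx, , drop = FALSE])
    } else colMeans(v$interior$vertices)
    IV[i] <- abs(cone_volume(v$interior, apex = apex, check_winding = FALSE))
    if (SV[i] <= 0)
      stop(sprintf("valve %d has nonpositive shell volume: check face orientation", i))
    if (IV[i] <= 0)
      stop(sprintf("valve %d has nonpositive internal volume", i))
    CS[i] <- centroid_size(if (!is.null(v$cloud)) v$cloud else v$whole)
  }
  k <- if (equivalve) 2 else 1
  TSV <- k * sum(SV); TIV <- k * sum(IV)
  structure(list(TSV = TSV, TIV = TIV, propSV = TSV / (TSV + TIV),
                 body_centroid_size = k * sum(CS),
                 equivalve = equivalve, SV = SV, IV = IV),
            class = "volume_summary")
}

#' @export
print.volume_summary <- function(x, ...) {
  cat(sprintf("volume_summary (%s): TSV %.4f, TIV %.4f, propSV %.4f, body centroid size %.4f\n",
              if (x$equivalve) "equivalve" else "inequivalve",
              x$TSV, x$TIV, x$propSV, x$body_centroid_size))
  invisible(x)
}
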