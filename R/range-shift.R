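# Trait range-shift analysis between two regions: per-trait scaling (not
# centering), per-subgroup changes in minima and maxima, and the nine-field
# classification of range change.

#' Scale trait columns without centering
#'
#' Each trait column is divided by its sample standard deviation so changes
#' across traits are in comparable units (standard deviations); means keep
#' their sign because no centering is applied.
#'
#' @param traits numeric matrix or data.frame, species x traits.
#' @return matrix with unit-SD columns.
#' @export
scale_not_center <- function(traits) {
  M <- as.matrix(traits)
  sds <- apply(M, 2, stats::sd)
  bad <- which(!(sds > 0))
  if (length(bad))
    stop("zero-variance trait: ", paste(colnames(M)[bad] %||% bad, collapse = ", "))
  sweep(M, 2, sds, `/`)
}

#' Per-subgroup changes in trait minima and maxima between regions
#'
#' For every eligible subgroup (the whole fauna plus each family or
#' functional group with more than `min_n - 1` species in both regions), the
#' change in the minimum scaled trait value is `min(focal) - min(reference)`
#' and likewise for the maximum. With the Florida Keys as focal region and
#' the Gulf of Maine as reference, positive deltas mean larger FK values.
#'
#' @param scaled numeric vector (one scaled trait) or single-column matrix.
#' @param region region label per species; exactly two regions.
#' @param subgroup subgroup label per species (family or functional group).
#' @param focal focal region name; default the first of `sort(unique(region))`.
#' @param kind label recorded for the subgroup column, e.g. `"family"`.
#' @param min_n minimum species per region for inclusion, default 3
#'   (the ">2 species in both regions" rule).
#' @param include_fauna include the whole-fauna point, default `TRUE`.
#' @return data.frame: `subgroup`, `kind`, `n_focal`, `n_ref`, `delta_min`,
#'   `delta_max`; excluded subgroups are reported in the `"excluded"`
#'   attribute.
#' @export
range_deltas <- function(scaled, region, subgroup, focal = NULL,
                         kind = "subgroup", min_n = 3L, include_fauna = TRUE) {
  x <- as.numeric(as.matrix(scaled))
  region <- as.character(region)
  regs <- sort(unique(region))
  if (length(regs) != 2L) stop("exactly two regions are required")
  if (is.null(focal)) focal <- regs[1]
  ref <- setdiff(regs, focal)
  subgroup <- as.character(subgroup)
  one <- function(mask, label, klab) {
    xf <- x[mask & region == focal]; xr <- x[mask & region == ref]
    if (length(xf) < min_n || length(xr) < min_n) return(NULL)
    data.frame(subgroup = label, kind = klab,
               n_focal = length(xf), n_ref = length(xr),
               delta_min = min(xf) - min(xr),
               delta_max = max(xf) - max(xr))
  }
  rows <- list()
  if (include_fauna)
    rows <- c(rows, list(one(rep(TRUE, length(x)), "whole-fauna", "fauna")))
  sgs <- sort(unique(subgroup))
  res <- lapply(sgs, function(g) one(subgroup == g, g, kind))
  rows <- c(rows, res)
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  excluded <- sgs[vapply(res, is.null, TRUE)]
  if (length(excluded))
    message("excluded (too few species in a region): ",
            paste(excluded, collapse = ", "))
  attr(out, "excluded") <- excluded
  attr(out, "focal") <- focal
  attr(out, "reference") <- ref
  out
}

field_codes <- c("-" = 1L, "0" = 2L, "+" = 3L)

field_descriptions <- c(
  "min-/max-" = "range shifted down (lower minimum and maximum in focal region)",
  "min-/max0" = "expansion downward, bounded maximum",
  "min-/max+" = "range expansion at both ends in focal region",
  "min0/max-" = "contraction from above: decreased maxima, bounded minima",
  "min0/max0" = "no interpretable difference between regions",
  "min0/max+" = "expansion upward, bounded minimum (focal greater maximum)",
  "min+/max-" = "contraction from both ends in focal region",
  "min+/max0" = "contraction from below, bounded maximum",
  "min+/max+" = "range shifted up (greater minimum and maximum in focal region)")

#' Nine-field classification of range shifts
#'
#' The bivariate (delta-min, delta-max) space is divided into nine fields by
#' the first positive and negative standard deviations of the deltas from
#' their mean on each axis. Deltas within one standard deviation of the mean
#' (boundaries inclusive) fall in the central band of that axis; the central
#' field is interpreted as "no interpretable difference". Threshold
#' statistics exclude the whole-fauna point by default, since it is a
#' reference marker, not a subgroup.
#'
#' @param shifts data.frame from [range_deltas()].
#' @param exclude_fauna drop `kind == "fauna"` rows from the threshold mean
#'   and SD (default `TRUE`); such rows are still classified.
#' @return the input with added `field` (e.g. `"min0/max-"`) and
#'   `field_description` columns; threshold statistics are attached as the
#'   `"thresholds"` attribute (a data.frame with one row per axis).
#' @export
classify_fields <- function(shifts, exclude_fauna = TRUE) {
  stopifnot(all(c("delta_min", "delta_max") %in% names(shifts)))
  base <- if (exclude_fauna && "kind" %in% names(shifts))
    shifts[shifts$kind != "fauna", , drop = FALSE] else shifts
  if (nrow(base) < 2L)
    stop("at least 2 subgroups are needed to define the field thresholds")
  thr <- do.call(rbind, lapply(c("delta_min", "delta_max"), function(ax) {
    m <- mean(base[[ax]]); s <- stats::sd(base[[ax]])
    data.frame(axis = ax, mean = m, sd = s, low = m - s, high = m + s)
  }))
  band <- function(x, lo, hi) ifelse(x < lo, "-", ifelse(x > hi, "+", "0"))
  bmin <- band(shifts$delta_min, thr$low[1], thr$high[1])
  bmax <- band(shifts$delta_max, thr$low[2], thr$high[2])
  shifts$field <- paste0("min", bmin, "/max", bmax)
  shifts$field_description <- unname(field_descriptions[shifts$field])
  attr(shifts, "thresholds") <- thr
  class(shifts) <- c("range_shift", class(shifts))
  shifts
}

#' @export
print.range_shift <- function(x, ...) {
  cat("range_shift classification (focal minus reference, scaled trait units)\n")
  print(as.data.frame(x)[, c("subgroup", "kind", "n_focal", "n_ref",
                             "delta_min", "delta_max", "field")],
        row.names = FALSE)
  thr <- attr(x, "thresholds")
  if (!is.null(thr)) {
    cat("thresholds:\n"); print(thr, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the nine-field range-shift partition
#'
#' @param x a classified `range_shift` data.frame.
#' @param ... passed to `plot()`.
#' @export
plot.range_shift <- function(x, ...) {
  thr <- attr(x, "thresholds")
  plot(x$delta_min, x$delta_max, pch = ifelse(x$kind == "fauna", 8, 19),
       xlab = "change in minimum (SD units)",
       ylab = "change in maximum (SD units)", ...)
  graphics::abline(v = c(thr$low[1], thr$high[1]),
                   h = c(thr$low[2], thr$high[2]), lty = 2, col = "grey50")
  invisible(x)
}
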