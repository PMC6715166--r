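# Morphospace construction (PCA, power analysis, back-projection) and
# between-group statistics: sum of variances, median minimum-spanning-tree
# distance, cumulative PC-score ranges, reshuffling null models, and
# Wilcoxon / Kolmogorov-Smirnov tests.

flatten_grids <- function(aligned) {
  if (inherits(aligned, "procrustes_set")) {
    X <- t(vapply(aligned$aligned, function(m) as.vector(t(m)),
                  numeric(3 * nrow(aligned$aligned[[1]]))))
    rownames(X) <- aligned$specimen_ids
    X
  } else as.matrix(aligned)
}

#' Principal-component morphospace of Procrustes-aligned grids
#'
#' Centered (not variance-scaled) PCA of the flattened aligned coordinates.
#' The number of retained axes can be fixed (23 in the standard protocol),
#' chosen by a cumulative explained-variance threshold, or by stabilization
#' of the reconstruction RMSE.
#'
#' @param aligned a `procrustes_set`, or a specimens-by-coordinates matrix.
#' @param n_axes axis retention policy: a fixed count (default 23, capped at
#'   the available rank), `"variance"` (smallest k reaching `var_threshold`),
#'   or `"rmse"` (smallest k whose median per-specimen reconstruction RMSE
#'   improvement falls below 1% of the full-rank RMSE drop).
#' @param var_threshold cumulative explained-variance target for the
#'   `"variance"` policy, default 0.95.
#' @return an object of class `morphospace`: `scores`, `rotation`,
#'   `explained` (variance fractions), `center` (mean shape), `sdev`,
#'   `n_axes`.
#' @export
pca_morphospace <- function(aligned, n_axes = 23L, var_threshold = 0.95) {
  X <- flatten_grids(aligned)
  if (nrow(X) < 3L) stop("morphospace needs at least 3 specimens")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k_avail <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- if (is.character(n_axes)) {
    policy <- match.arg(n_axes, c("variance", "rmse"))
    if (policy == "variance") {
      min(which(cumsum(expl) >= var_threshold))
    } else {
      rm_full <- rmse_by_rank(pc, X, k_avail)
      drops <- -diff(c(rm_full, 0))
      cand <- which(drops <= 0.01 * (rm_full[1] - rm_full[k_avail]))
      if (length(cand)) cand[1] else k_avail
    }
  } else min(as.integer(n_axes), k_avail)
  structure(list(scores = pc$scores %||% pc$x, rotation = pc$rotation,
                 explained = expl, center = pc$center, sdev = pc$sdev,
                 n_axes = k),
            class = "morphospace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rmse_by_rank <- function(pc, X, kmax) {
  vapply(seq_len(kmax), function(k) {
    Xh <- pc$x[, seq_len(k), drop = FALSE] %*% t(pc$rotation[, seq_len(k), drop = FALSE])
    Xh <- sweep(Xh, 2, pc$center, `+`)
    stats::median(sqrt(rowMeans((X - Xh)^2)))
  }, 0)
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("morphospace: %d specimens, %d axes retained (PC1 %.1f%%, PC2 %.1f%%, cumulative %.1f%%)\n",
              nrow(x$scores), x$n_axes, 100 * x$explained[1],
              100 * x$explained[2],
              100 * sum(x$explained[seq_len(x$n_axes)])))
  invisible(x)
}

#' Per-specimen reconstruction RMSE from the leading k axes
#'
#' Root mean squared error between each specimen's true flattened
#' configuration and its rank-`k` PCA reconstruction; the power-analysis
#' quantity whose stabilization guides axis retention.
#'
#' @param space a `morphospace`.
#' @param k number of leading axes used for reconstruction.
#' @return numeric vector, one RMSE per specimen.
#' @export
reconstruction_rmse <- function(space, k) {
  stopifnot(k >= 1, k <= ncol(space$scores))
  S <- space$scores[, seq_len(k), drop = FALSE]
  Xh <- S %*% t(space$rotation[, seq_len(k), drop = FALSE])
  full <- space$scores %*% t(space$rotation)
  sqrt(rowMeans((full - Xh)^2))
}

#' Back-project a score vector to a shape configuration
#'
#' Mean shape plus the rotation matrix applied to the (zero-padded) score
#' vector; the zero vector returns the mean shape exactly. Used to
#' visualize shells at arbitrary morphospace positions.
#'
#' @param space a `morphospace`.
#' @param pc_point numeric score vector, length at most the number of axes.
#' @return flattened configuration (numeric vector, length 3 x landmarks).
#' @export
back_project <- function(space, pc_point) {
  k <- length(pc_point)
  if (k > ncol(space$rotation)) stop("score vector longer than available axes")
  padded <- c(pc_point, rep(0, ncol(space$rotation) - k))
  as.vector(space$rotation %*% padded) + space$center
}

# ---------------------------------------------------------------------------
# Disparity statistics
# ---------------------------------------------------------------------------

#' Deterministic Euclidean minimum spanning tree
#'
#' Kruskal's algorithm on exact pairwise distances with lexicographic
#' tie-breaking on the edge index, so the tree is reproducible even on
#' degenerate point sets.
#'
#' @param X `n x d` matrix of coordinates.
#' @return `(n-1) x 3` matrix with columns `i`, `j`, `weight`.
#' @export
euclidean_mst <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  e <- cpp_mst_edges(X)
  colnames(e) <- c("i", "j", "weight")
  e
}

#' Disparity metrics of one group in morphospace
#'
#' Three summaries over the retained axes: the sum of per-axis sample
#' variances (morphological disparity), the median edge length of the
#' Euclidean minimum spanning tree over the group's specimens (dispersion /
#' stacking), and the cumulative sum of per-axis score ranges (a tractable
#' stand-in for total morphospace occupation in high dimensions).
#'
#' @param scores group's specimens-by-axes score matrix (axes 1..23 in the
#'   standard protocol).
#' @return list with `sum_of_variances`, `median_mst_edge`,
#'   `cumulative_range`, and `mst_edges` (edge lengths).
#' @export
disparity_metrics <- function(scores) {
  S <- as.matrix(scores)
  if (nrow(S) < 2L) stop("disparity metrics need at least 2 specimens")
  vars <- apply(S, 2, stats::var)          # sample (n-1) variance
  mst <- euclidean_mst(S)
  rngs <- apply(S, 2, function(x) diff(range(x)))
  list(sum_of_variances = sum(vars),
       median_mst_edge = stats::median(mst[, "weight"]),
       cumulative_range = sum(rngs),
       mst_edges = mst[, "weight"])
}

group_metric <- function(S, which_metric) {
  switch(which_metric,
         sum_of_variances = {
           n <- nrow(S)
           sum(colSums(S * S) - n * colMeans(S)^2) / (n - 1)
         },
         median_mst_edge = stats::median(euclidean_mst(S)[, "weight"]),
         cumulative_range = {
           sum(vapply(seq_len(ncol(S)), function(j) {
             x <- S[, j]; max(x) - min(x)
           }, 0))
         },
         stop("unknown metric: ", which_metric))
}

#' Reshuffling null model for a group-wise disparity statistic
#'
#' Permutes the group labels across specimens (preserving group sizes),
#' recomputes the statistic for each group under each permutation, and
#' returns the permutation mean and percentile 95% confidence interval per
#' group, alongside the observed values.
#'
#' @param scores specimens-by-axes matrix.
#' @param labels group (e.g. region) label per specimen.
#' @param statistic `"sum_of_variances"`, `"median_mst_edge"`,
#'   `"cumulative_range"`, or a function `(scores) -> scalar`.
#' @param n_perm number of reshuffles, default 1000.
#' @param seed RNG seed, default 0.
#' @param conf confidence level for the percentile interval, default 0.95.
#' @return data.frame with one row per group: `group`, `n`, `observed`,
#'   `null_mean`, `ci_lo`, `ci_hi`; the permutation draws are attached as
#'   attribute `"draws"` (groups x permutations).
#' @export
permutation_null <- function(scores, labels, statistic = "sum_of_variances",
                             n_perm = 1000L, seed = 0L, conf = 0.95) {
  S <- as.matrix(scores)
  labels <- as.character(labels)
  if (length(labels) != nrow(S)) stop("labels must match score rows")
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 group labels")
  if (n_perm < 100L) warning("fewer than 100 permutations: unstable null interval")
  stat_fun <- if (is.function(statistic)) statistic else {
    nm <- match.arg(statistic,
                    c("sum_of_variances", "median_mst_edge", "cumulative_range"))
    function(S) group_metric(S, nm)
  }
  observed <- vapply(groups, function(g) stat_fun(S[labels == g, , drop = FALSE]), 0)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = length(groups), ncol = n_perm,
                  dimnames = list(groups, NULL))
  for (p in seq_len(n_perm)) {
    lab <- sample(labels)
    for (gi in seq_along(groups))
      draws[gi, p] <- stat_fun(S[lab == groups[gi], , drop = FALSE])
  }
  alpha <- (1 - conf) / 2
  out <- data.frame(
    group = groups,
    n = as.integer(table(factor(labels, levels = groups))),
    observed = observed,
    null_mean = rowMeans(draws),
    ci_lo = apply(draws, 1, stats::quantile, probs = alpha, names = FALSE),
    ci_hi = apply(draws, 1, stats::quantile, probs = 1 - alpha, names = FALSE),
    row.names = NULL)
  attr(out, "draws") <- draws
  out
}

#' Pairwise disparity and dispersion tests between two groups
#'
#' Disparity: a Wilcoxon rank-sum test (midranks for ties) on the
#' per-specimen disparity contributions — squared deviations from the own
#' group's centroid by default, plain distances optionally — with an
#' optional Bonferroni correction across `m` simultaneous comparisons.
#' Dispersion: a two-sample Kolmogorov-Smirnov test on the two groups'
#' minimum-spanning-tree edge-length distributions.
#'
#' @param scoresA,scoresB score matrices of the two groups (>= 3 specimens
#'   each).
#' @param mstA,mstB optional precomputed MST edge-length vectors; computed
#'   from the scores when missing.
#' @param m number of simultaneous comparisons for the Bonferroni
#'   correction, default 1 (no correction).
#' @param deviations `"squared"` (default) or `"distance"` contributions.
#' @return list with `wilcoxon_p`, `wilcoxon_p_adjusted`, `ks_p`, `ks_D`.
#' @export
group_tests <- function(scoresA, scoresB, mstA = NULL, mstB = NULL, m = 1L,
                        deviations = c("squared", "distance")) {
  deviations <- match.arg(deviations)
  A <- as.matrix(scoresA); B <- as.matrix(scoresB)
  if (nrow(A) < 3L || nrow(B) < 3L) stop("both groups need at least 3 specimens")
  dev_of <- function(S) {
    d2 <- rowSums(sweep(S, 2, colMeans(S))^2)
    if (deviations == "squared") d2 else sqrt(d2)
  }
  da <- dev_of(A); db <- dev_of(B)
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    warning("zero-variance group: Wilcoxon p undefined")
    wp <- NA_real_
  } else {
    wp <- suppressWarnings(stats::wilcox.test(da, db, exact = FALSE)$p.value)
  }
  if (is.null(mstA)) mstA <- euclidean_mst(A)[, "weight"]
  if (is.null(mstB)) mstB <- euclidean_mst(B)[, "weight"]
  ks <- suppressWarnings(stats::ks.test(mstA, mstB))
  list(wilcoxon_p = wp,
       wilcoxon_p_adjusted = if (is.na(wp)) NA_real_ else min(1, m * wp),
       ks_p = unname(ks$p.value), ks_D = unname(ks$statistic))
}

#' Disparity summary of groups with null models and tests
#'
#' Convenience wrapper running [disparity_metrics()] per group,
#' [permutation_null()] for each statistic, and pairwise [group_tests()]
#' (Bonferroni-corrected across the pairs tested).
#'
#' @param scores specimens-by-axes score matrix.
#' @param labels group label per specimen.
#' @param n_perm reshuffles per statistic, default 1000.
#' @param seed RNG seed, default 0.
#' @param min_n groups below this size are dropped, default 3 (the ">2
#'   species in both regions" inclusion rule).
#' @return object of class `disparity_summary`: `observed` (data.frame),
#'   `nulls` (list of permutation tables per statistic), `tests`
#'   (data.frame of pairwise p-values), `excluded` (group labels dropped).
#' @export
disparity_summary <- function(scores, labels, n_perm = 1000L, seed = 0L,
                              min_n = 3L) {
  S <- as.matrix(scores)
  labels <- as.character(labels)
  sizes <- table(labels)
  keep_groups <- names(sizes)[sizes >= min_n]
  excluded <- setdiff(names(sizes), keep_groups)
  keep <- labels %in% keep_groups
  S <- S[keep, , drop = FALSE]; labels <- labels[keep]
  if (length(keep_groups) < 2L) stop("fewer than 2 groups meet the size rule")
  obs <- do.call(rbind, lapply(sort(keep_groups), function(g) {
    dm <- disparity_metrics(S[labels == g, , drop = FALSE])
    data.frame(group = g, n = sum(labels == g),
               sum_of_variances = dm$sum_of_variances,
               median_mst_edge = dm$median_mst_edge,
               cumulative_range = dm$cumulative_range)
  }))
  stats_names <- c("sum_of_variances", "median_mst_edge", "cumulative_range")
  nulls <- lapply(setNames(stats_names, stats_names), function(st)
    permutation_null(S, labels, st, n_perm = n_perm, seed = seed))
  prs <- utils::combn(sort(keep_groups), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(prs, function(pr) {
    gt <- group_tests(S[labels == pr[1], , drop = FALSE],
                      S[labels == pr[2], , drop = FALSE], m = length(prs))
    data.frame(groupA = pr[1], groupB = pr[2],
               wilcoxon_p = gt$wilcoxon_p,
               wilcoxon_p_bonferroni = gt$wilcoxon_p_adjusted,
               ks_D = gt$ks_D, ks_p = gt$ks_p)
  }))
  structure(list(observed = obs, nulls = nulls, tests = tests,
                 excluded = excluded, n_perm = n_perm, seed = seed),
            class = "disparity_summary")
}

#' @export
print.disparity_summary <- function(x, ...) {
  cat("disparity_summary\n observed:\n")
  print(x$observed, row.names = FALSE)
  cat(sprintf(" nulls: %d reshuffles (seed %d)\n tests:\n", x$n_perm, x$seed))
  print(x$tests, row.names = FALSE)
  if (length(x$excluded))
    cat(" excluded groups (size rule):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a two-axis morphospace
#'
#' Scatter of specimens on two principal components, optionally colored by
#' group, with the minimum spanning tree of each group overlaid.
#'
#' @param x a `morphospace`.
#' @param axes which two axes to plot, default `c(1, 2)`.
#' @param labels optional group label per specimen.
#' @param mst overlay each group's MST, default `TRUE`.
#' @param ... passed to `plot()`.
#' @export
plot.morphospace <- function(x, axes = c(1, 2), labels = NULL, mst = TRUE, ...) {
  S <- x$scores[, axes, drop = FALSE]
  cols <- if (is.null(labels)) rep(1L, nrow(S)) else as.integer(factor(labels))
  plot(S, col = cols, pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", axes[1], 100 * x$explained[axes[1]]),
       ylab = sprintf("PC%d (%.1f%%)", axes[2], 100 * x$explained[axes[2]]), ...)
  if (mst && !is.null(labels)) {
    for (g in unique(labels)) {
      Sg <- x$scores[labels == g, seq_len(x$n_axes), drop = FALSE]
      if (nrow(Sg) < 2) next
      e <- euclidean_mst(Sg)
      P <- Sg[, axes, drop = FALSE]
      segments(P[e[, 1], 1], P[e[, 1], 2], P[e[, 2], 1], P[e[, 2], 2],
               col = as.integer(factor(g, levels = unique(labels))))
    }
  }
  invisible(x)
}

#' @importFrom graphics segments
NULL
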