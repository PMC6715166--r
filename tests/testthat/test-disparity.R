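# PCA morphospace, reconstruction, back-projection, disparity statistics,
# reshuffling nulls and the two-group tests.

test_that("PCA morphospace is centered, complete, and ranks variance correctly", {
  # specimens on a line: PC1 explains everything
  t <- seq(-1, 1, length.out = 6)
  X <- outer(t, c(1, 2, -1, 0.5))
  ms <- pca_morphospace(X, n_axes = 2)
  expect_equal(ms$explained[1], 1, tolerance = 1e-12)
  expect_equal(colMeans(ms$scores), rep(0, ncol(ms$scores)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diff(ms$explained) <= 1e-12))

  # isotropic Gaussian cloud: roughly equal explained variances
  set.seed(3)
  G <- matrix(rnorm(3000), 1000, 3)
  msg <- pca_morphospace(G, n_axes = 3)
  expect_true(all(abs(msg$explained - 1 / 3) < 0.05))

  # completeness: reconstruction from all PCs returns the data
  set.seed(4)
  Y <- matrix(rnorm(20 * 7), 20, 7)
  msy <- pca_morphospace(Y, n_axes = 7)
  rec <- sweep(msy$scores %*% t(msy$rotation), 2, msy$center, `+`)
  expect_equal(rec, Y, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_morphospace(Y[1:2, ]), "at least 3")
})

test_that("reconstruction RMSE is nonincreasing in k and zero at full rank", {
  set.seed(8)
  n <- 15
  # rank-2 data plus nothing: RMSE hits zero at k = 2
  basis <- matrix(rnorm(2 * 30), 2, 30)
  low <- matrix(rnorm(n * 2), n, 2) %*% basis
  ms_low <- pca_morphospace(low, n_axes = 10)
  expect_lt(max(reconstruction_rmse(ms_low, 2)), 1e-10)

  Y <- matrix(rnorm(n * 12), n, 12)
  ms <- pca_morphospace(Y, n_axes = 12)
  kmax <- sum(ms$sdev > 1e-10)
  rms <- sapply(seq_len(kmax), function(k) reconstruction_rmse(ms, k))
  # per-specimen monotone decrease
  expect_true(all(apply(rms, 1, function(x) all(diff(x) <= 1e-10))))
  expect_lt(max(rms[, kmax]), 1e-8)
})

test_that("back-projection inverts scores and varies smoothly over the plane", {
  set.seed(12)
  Y <- matrix(rnorm(12 * 9), 12, 9)
  ms <- pca_morphospace(Y, n_axes = 9)
  expect_equal(back_project(ms, numeric(ncol(ms$scores))), ms$center,
               ignore_attr = TRUE)
  for (i in c(1, 5, 12))
    expect_equal(back_project(ms, ms$scores[i, ]), Y[i, ], tolerance = 1e-8,
                 ignore_attr = TRUE)
  # adjacent grid points in PC1-2 are closer in shape than distant ones
  near <- sqrt(mean((back_project(ms, c(0.1, 0)) - back_project(ms, c(0.2, 0)))^2))
  far <- sqrt(mean((back_project(ms, c(0.1, 0)) - back_project(ms, c(2, 0)))^2))
  expect_lt(near, far)
  expect_error(back_project(ms, numeric(50)), "longer")
})

test_that("disparity metrics match closed forms and the exhaustive MST oracle", {
  dm <- disparity_metrics(matrix(c(0, 2), 2, 1))
  expect_equal(dm$sum_of_variances, 2)     # sample (n-1) variance
  expect_equal(dm$cumulative_range, 2)
  expect_equal(dm$median_mst_edge, 2)

  # collinear 1-D points {0, 1, 3}: MST edges {1, 2}, median 1.5
  dm2 <- disparity_metrics(matrix(c(0, 1, 3), 3, 1))
  expect_equal(sort(euclidean_mst(matrix(c(0, 1, 3)))[, "weight"]), c(1, 2))
  expect_equal(dm2$median_mst_edge, 1.5)

  # exhaustive spanning-tree enumeration oracle, n <= 7
  set.seed(33)
  for (rep in 1:6) {
    n <- sample(5:7, 1)
    X <- matrix(runif(n * 2), n, 2)
    e <- euclidean_mst(X)
    oracle <- brute_mst(X)
    expect_equal(sum(e[, "weight"]), oracle$total, tolerance = 1e-12)
    expect_equal(sort(e[, "weight"]), oracle$edge_weights, tolerance = 1e-12)
  }

  # independent library cross-check on a larger set
  set.seed(34)
  X <- matrix(rnorm(40 * 3), 40, 3)
  e <- euclidean_mst(X)
  sp <- vegan::spantree(dist(X))
  expect_equal(sum(e[, "weight"]), sum(sp$dist), tolerance = 1e-10)
  expect_error(disparity_metrics(matrix(1, 1, 3)), "at least 2")
})

test_that("sum of variances and MST stats are rotation-invariant; ranges are not", {
  set.seed(44)
  X <- matrix(rnorm(20 * 4), 20, 4)
  th <- 0.9
  R <- diag(4); R[1:2, 1:2] <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  d1 <- disparity_metrics(X); d2 <- disparity_metrics(X %*% R)
  expect_equal(d2$sum_of_variances, d1$sum_of_variances, tolerance = 1e-10)
  expect_equal(d2$median_mst_edge, d1$median_mst_edge, tolerance = 1e-10)
  expect_gt(abs(d2$cumulative_range - d1$cumulative_range), 1e-6)
})

test_that("reshuffling nulls are seeded, symmetric, and degenerate when they must be", {
  set.seed(55)
  S <- matrix(rnorm(30 * 4), 30, 4)
  lab <- rep(c("FK", "GM"), c(18, 12))
  pn <- permutation_null(S, lab, "sum_of_variances", n_perm = 300, seed = 2)
  pn2 <- permutation_null(S, lab, "sum_of_variances", n_perm = 300, seed = 2)
  expect_identical(pn, pn2)
  expect_true(all(pn$ci_lo <= pn$ci_hi))

  # swapping group labels swaps the group summaries exactly
  lab_sw <- ifelse(lab == "FK", "GM", "FK")
  pn_sw <- permutation_null(S, lab_sw, "sum_of_variances", n_perm = 300, seed = 2)
  expect_equal(pn$observed[pn$group == "FK"],
               pn_sw$observed[pn_sw$group == "GM"])

  # a label-invariant statistic has a degenerate null at the observed value
  whole_var <- function(S_) sum(apply(S, 2, var))  # ignores the subset
  pw <- permutation_null(S, lab, whole_var, n_perm = 100, seed = 1)
  expect_equal(pw$ci_lo, pw$observed, tolerance = 1e-12)
  expect_equal(pw$ci_hi, pw$observed, tolerance = 1e-12)

  # identical specimens: all statistics 0, CI = [0, 0]
  S0 <- matrix(1, 20, 3)
  p0 <- permutation_null(S0, rep(c("A", "B"), 10), "sum_of_variances",
                         n_perm = 100, seed = 1)
  expect_equal(p0$observed, c(0, 0), ignore_attr = TRUE)
  expect_equal(p0$ci_lo, c(0, 0), ignore_attr = TRUE)
  expect_equal(p0$ci_hi, c(0, 0), ignore_attr = TRUE)
  expect_warning(permutation_null(S, lab, "sum_of_variances", n_perm = 50,
                                  seed = 1), "100")
})

test_that("two-group tests behave on identical, separated, and corrected cases", {
  set.seed(66)
  A <- matrix(rnorm(12 * 3), 12, 3)
  gt_same <- group_tests(A, A)
  expect_equal(gt_same$ks_D, 0)
  expect_gt(gt_same$wilcoxon_p, 0.999)

  # tight cluster vs dispersed cluster: strongly different deviations
  B <- 25 * matrix(rnorm(12 * 3), 12, 3)
  gt_diff <- group_tests(A, B)
  expect_lt(gt_diff$wilcoxon_p, 0.001)
  # Bonferroni: adjusted p = min(1, m p)
  gt_m <- group_tests(A, B, m = 7)
  expect_equal(gt_m$wilcoxon_p_adjusted,
               min(1, 7 * gt_m$wilcoxon_p), tolerance = 1e-12)

  # zero-variance group
  Z <- matrix(1, 5, 3)
  expect_warning(gz <- group_tests(Z, A), "zero-variance")
  expect_true(is.na(gz$wilcoxon_p))
  expect_error(group_tests(A[1:2, ], B), "at least 3")
})

test_that("the disparity summary applies the subgroup size rule", {
  set.seed(77)
  S <- matrix(rnorm(25 * 5), 25, 5)
  lab <- c(rep("FK", 12), rep("GM", 11), rep("XX", 2))  # XX below the rule
  ds <- disparity_summary(S, lab, n_perm = 150, seed = 3)
  expect_equal(ds$excluded, "XX")
  expect_equal(sort(ds$observed$group), c("FK", "GM"))
  expect_equal(nrow(ds$tests), 1L)
  expect_true(all(c("sum_of_variances", "median_mst_edge", "cumulative_range")
                  %in% names(ds$nulls)))
  expect_equal(ncol(attr(ds$nulls$sum_of_variances, "draws")), 150L)
})
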