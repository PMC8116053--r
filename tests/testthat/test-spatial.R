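test_that("mean_nnd is the mean distance to each point's nearest neighbor", {
  expect_equal(mean_nnd(rbind(c(0, 0), c(10, 0))), 10)
  expect_equal(mean_nnd(rbind(c(0, 0), c(10, 0), c(30, 0))), mean(c(10, 10, 20)))
  expect_equal(mean_nnd(rbind(c(5, 5), c(5, 5))), 0)
  expect_error(mean_nnd(rbind(c(0, 0))), "2 points")
  # rigid-motion invariance
  set.seed(1)
  pts <- matrix(runif(20, 0, 100), ncol = 2)
  th <- 0.7
  rot <- pts %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) + 42
  expect_equal(mean_nnd(pts), mean_nnd(rot), tolerance = 1e-9)
})

test_that("CSR null NND matches the two-point uniform-square expectation", {
  # E[distance of 2 uniform points in the unit square] ~ 0.52141 um
  sq <- unit_square_nm(1000)
  pat <- point_pattern(rbind(c(100, 100), c(900, 900)), sq)
  res <- csr_null_nnd(pat, n_reps = 2000, seed = 7)
  se <- sd(res$null_means_nm) / sqrt(res$n_reps)
  expect_lt(abs(res$null_nnd_nm - 521.41), 3 * se)
  expect_equal(res$observed_nnd_nm, sqrt(2) * 800)
})

test_that("clustered patterns sit below their CSR null NND", {
  poly <- gen_az_polygon(0.071, 8, 0.2, seed = 2)
  clu <- gen_point_pattern(poly, "clustered", 26, 5, 5, seed = 3)
  res <- csr_null_nnd(clu, n_reps = 100, seed = 4)
  expect_lt(res$observed_nnd_nm, res$null_nnd_nm)
  # a CSR pattern is consistent with its own null
  csr <- gen_point_pattern(poly, "CSR", 26, seed = 5)
  res0 <- csr_null_nnd(csr, n_reps = 100, seed = 6)
  expect_lt(
    abs(res0$observed_nnd_nm - res0$null_nnd_nm),
    3 * sd(res0$null_means_nm)
  )
})

test_that("signed-rank test matches exact enumeration and stats::wilcox.test", {
  same <- wilcoxon_signed_rank(1:6, 1:6)
  expect_true(same$all_zero)
  expect_equal(same$p, 1)
  # all six differences positive: 2/2^6 by enumeration
  allpos <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6) + 10, rep(10, 6))
  expect_equal(allpos$p, 2 / 64)
  # antisymmetric differences center the statistic
  anti <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_gt(anti$p, 0.5)
  # oracle: stats::wilcox.test on tie-free data (exact branch)
  set.seed(8)
  a <- rnorm(12)
  b <- rnorm(12)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, unname(ref$p.value))
  expect_equal(ours$statistic, unname(ref$statistic))
  # oracle for the normal-approximation branch (n > 25)
  a <- rnorm(40)
  b <- rnorm(40, 0.3)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-10)
})

test_that("Ripley H detects clustering, regularity and CSR", {
  sq <- unit_square_nm(500)
  # one tight Gaussian cluster: strong positive H at 20-50 nm
  clu <- gen_point_pattern(sq, "clustered", 30, 1, 10, seed = 9)
  h <- ripley_h(clu, radii_nm = seq(5, 100, by = 5))
  expect_gt(min(h$h[h$r_nm >= 20 & h$r_nm <= 50]), 0)
  # hexagonal lattice: negative H below the lattice spacing
  g <- expand.grid(i = 0:7, j = 0:7)
  hx <- cbind(60 * (g$i + 0.5 * (g$j %% 2)) + 30, 60 * sqrt(3) / 2 * g$j + 30)
  hx <- hx[hx[, 1] <= 500 & hx[, 2] <= 500, ]
  lat <- point_pattern(hx, sq)
  hl <- ripley_h(lat, radii_nm = seq(5, 55, by = 5))
  expect_lt(max(hl$h[hl$r_nm <= 50]), 0)
  # CSR stays inside a 3-SD envelope from matched simulations
  csr <- gen_point_pattern(sq, "CSR", 200, seed = 10)
  radii <- seq(10, 200, by = 10)
  hc <- ripley_h(csr, radii_nm = radii)$h
  sims <- vapply(
    1:50,
    function(i) ripley_h(gen_point_pattern(sq, "CSR", 200, seed = 100 + i),
                         radii_nm = radii)$h,
    numeric(length(radii))
  )
  z <- abs(hc - rowMeans(sims)) / apply(sims, 1, sd)
  expect_lt(mean(z > 3), 0.05)
  expect_error(ripley_h(csr, radii_nm = c(100, 5000)), "diameter")
})

test_that("MAD test separates clustered from CSR patterns", {
  poly <- gen_az_polygon(0.071, 8, 0.2, seed = 3)
  clu <- gen_point_pattern(poly, "clustered", 26, 5, 15, seed = 11)
  mt <- mad_test(clu, n_sim = 99, seed = 7)
  expect_lt(mt$mad_p, 0.05)
  expect_true(mt$clustered)
  csr <- gen_point_pattern(poly, "CSR", 26, seed = 5)
  mt0 <- mad_test(csr, n_sim = 99, seed = 7)
  expect_gt(mt0$mad_p, 0.05)
  expect_false(mt0$clustered)
  # rank p-value floor: with 19 sims the smallest attainable p is 1/20 = 0.05,
  # which is not significant, so `clustered` can never fire
  mt19 <- mad_test(clu, n_sim = 19, seed = 7)
  expect_gte(mt19$mad_p, 0.05)
  expect_false(mt19$clustered)
  tiny <- point_pattern(rbind(c(0, 0), c(10, 10)), unit_square_nm())
  expect_error(mad_test(tiny), "5 points")
})

test_that("DBSCAN implements the stated neighborhood conventions", {
  # two 5-point groups 200 nm apart, intra-spacing 10 nm
  g1 <- cbind(seq(0, 40, 10), 0)
  g2 <- cbind(seq(0, 40, 10) + 240, 0)
  res <- dbscan(rbind(g1, g2), eps_nm = 31, min_pts = 2)
  expect_equal(res$n_clusters, 2L)
  expect_equal(sort(res$cluster_sizes), c(5L, 5L))
  # all pairwise distances beyond eps: everything is noise
  iso <- dbscan(rbind(c(0, 0), c(100, 0), c(0, 100)), eps_nm = 31, min_pts = 2)
  expect_equal(iso$n_clusters, 0L)
  expect_true(all(iso$labels == 0L))
  # density connectivity: a 30 nm chain is one cluster at eps = 31
  chain <- dbscan(cbind(seq(0, 300, 30), 0), eps_nm = 31, min_pts = 2)
  expect_equal(chain$n_clusters, 1L)
  expect_equal(chain$cluster_sizes, 11L)
  expect_equal(dbscan(matrix(numeric(0), ncol = 2), 31, 2)$n_clusters, 0L)
  expect_error(dbscan(g1, -1, 2), "eps")
})

test_that("DBSCAN at MinPts = 2 equals eps-graph connected components", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(2:50, 1)
    pts <- matrix(runif(2 * n, 0, 300), ncol = 2)
    eps <- runif(1, 10, 120)
    res <- dbscan(pts, eps, 2)
    oracle <- brute_components(pts, eps)
    expect_equal(res$n_clusters, oracle$n_clusters)
    expect_equal(sort(res$cluster_sizes), oracle$sizes)
    # permutation invariance of counts and sizes
    perm <- sample(n)
    res2 <- dbscan(pts[perm, , drop = FALSE], eps, 2)
    expect_equal(res2$n_clusters, res$n_clusters)
    expect_equal(sort(res2$cluster_sizes), sort(res$cluster_sizes))
  }
})

test_that("eps threshold semantics: a 2-point pattern links exactly at eps = d", {
  sq <- unit_square_nm(500)
  pat <- point_pattern(rbind(c(100, 100), c(140, 100)), sq)  # 40 nm apart
  sw <- eps_sweep(list(pat), eps_range_nm = c(35, 45), min_pts = 2, n_null = 2,
                  seed = 1)
  nc <- sw$profile$mean_nc_data
  expect_equal(nc[sw$profile$eps_nm == 39], 0)
  expect_equal(nc[sw$profile$eps_nm == 40], 1)
  expect_equal(nc[sw$profile$eps_nm == 45], 1)
})

test_that("eps_star increases with the generated cluster scale", {
  poly <- gen_az_polygon(0.071, 8, 0.2, seed = 4)
  star_at <- function(sigma) {
    pats <- lapply(1:8, function(i) {
      gen_point_pattern(poly, "clustered", 26, 5, sigma, seed = 50 * sigma + i)
    })
    eps_sweep(pats, min_pts = 2, n_null = 10, seed = 99)$eps_star
  }
  stars <- vapply(c(5, 10, 20), star_at, numeric(1))
  expect_true(all(diff(stars) > 0))
})

test_that("cluster metrics report density, occupancy and centroid spacing", {
  side <- sqrt(0.071) * 1000
  poly <- az_polygon(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
  # 5 well-separated tight clusters -> density 5/0.071 = 70.42 clusters/um^2
  centers <- rbind(c(50, 50), c(200, 50), c(50, 200), c(200, 200), c(125, 125))
  pts <- centers[rep(1:5, c(6, 5, 5, 5, 5)), ] +
    cbind(rep(c(0, 1, -1, 0, 0, 1), 5)[1:26], rep(c(0, 0, 0, 1, -1, 1), 5)[1:26])
  res <- dbscan(pts, eps_nm = 15, min_pts = 2)
  met <- cluster_metrics(res, poly)
  expect_equal(met$n_clusters, 5L)
  expect_equal(met$cluster_density_per_um2, 5 / 0.071, tolerance = 1e-12)
  expect_equal(sum(met$particles_per_cluster), 26L)
  # two centroids 85 nm apart: inter-cluster NND 85 for both
  two <- dbscan(rbind(c(0, 0), c(1, 0), c(85, 0), c(86, 0)), 5, 2)
  m2 <- cluster_metrics(two, poly)
  expect_equal(m2$intercluster_nnd_nm, c(85, 85), tolerance = 0.51)
  # single cluster: spacing undefined, flagged
  one <- dbscan(rbind(c(0, 0), c(5, 0)), 10, 2)
  m1 <- cluster_metrics(one, poly)
  expect_false(m1$intercluster_defined)
  expect_true(is.na(m1$mean_intercluster_nnd_nm))
  expect_equal(m1$cluster_density_per_um2, 1 / 0.071)
})

test_that("gold density is count over area", {
  poly <- gen_az_polygon(0.071, 8, 0, seed = 1)
  pat <- gen_point_pattern(poly, "CSR", 26, seed = 1)
  expect_equal(gold_density(pat), 26 / 0.071, tolerance = 1e-12)
  expect_equal(gold_density(point_pattern(NULL, poly)), 0)
  big <- gen_az_polygon(0.142, 8, 0, seed = 1)
  patb <- gen_point_pattern(big, "CSR", 26, seed = 1)
  expect_equal(gold_density(patb), gold_density(pat) / 2, tolerance = 1e-12)
})
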