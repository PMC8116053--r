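#' Mean nearest-neighbor distance of a point set
#'
#' Mean over points of the Euclidean distance to each point's nearest other
#' point.
#'
#' @param points_nm numeric matrix with columns (x, y) in nm; >= 2 rows.
#' @return mean NND in nm.
#' @export
mean_nnd <- function(points_nm) {
  p <- .as_points(points_nm)
  if (nrow(p) < 2L) stop("mean NND needs >= 2 points")
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Monte-Carlo CSR null for the mean NND of an AZ
#'
#' For each of `n_reps` replicates, the same number of points is placed
#' uniformly in the same AZ polygon and the mean NND computed; the null value
#' reported is the average of the per-replicate means (200 replicates per AZ
#' in the source protocol).
#'
#' @param pattern a [point_pattern()] with >= 2 points.
#' @param n_reps number of CSR replicates, >= 1.
#' @param seed integer seed.
#' @return Object of class `nnd_result`: `az_id`, `observed_nnd_nm`,
#'   `null_nnd_nm`, `null_means_nm` (per replicate), `n_points`, `n_reps`.
#' @export
csr_null_nnd <- function(pattern, n_reps = 200L, seed = 1L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n_points < 2L) stop("NND analysis needs >= 2 points")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  obs <- mean_nnd(pattern$points_nm)
  nulls <- with_seed(seed, {
    vapply(
      seq_len(n_reps),
      function(i) mean_nnd(.csr_points(pattern$polygon, pattern$n_points)),
      numeric(1L)
    )
  })
  structure(
    list(
      az_id = pattern$az_id, observed_nnd_nm = obs,
      null_nnd_nm = mean(nulls), null_means_nm = nulls,
      n_points = pattern$n_points, n_reps = as.integer(n_reps)
    ),
    class = "nnd_result"
  )
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test as used to compare per-AZ observed mean NNDs
#' with their CSR null means. Zero differences are dropped (Wilcoxon
#' convention); the exact null distribution is used for n <= 25 without ties,
#' the normal approximation with continuity and tie correction otherwise.
#'
#' @param paired_a,paired_b numeric vectors of equal length (>= 5 nonzero
#'   differences).
#' @return list with `statistic` (W, sum of positive-difference ranks), `p`
#'   (two-sided), `n` (nonzero differences), `exact`, `all_zero`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) stop("paired vectors differ in length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p = 1, n = 0L, exact = TRUE, all_zero = TRUE))
  }
  if (n < 5L) stop("need >= 5 nonzero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    mid <- n * (n + 1) / 4
    p <- if (W > mid) {
      2 * psignrank(W - 1, n, lower.tail = FALSE)
    } else {
      2 * psignrank(W, n)
    }
    p <- min(1, p)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = W, p = p, n = n, exact = exact, all_zero = FALSE)
}

# Correction window for the translation edge correction: the polygon itself
# when convex, its convex hull otherwise (documented approximation).
.correction_window <- function(polygon, warn = TRUE) {
  v <- polygon$vertices_nm
  if (.is_convex(v)) return(v)
  if (warn) {
    warning("non-convex AZ polygon: translation correction uses its convex hull")
  }
  v[rev(grDevices::chull(v)), , drop = FALSE]
}

.default_radii <- function(polygon, n_radii = 40L) {
  rmax <- sqrt(polygon$area_nm2) / 2
  seq(rmax / n_radii, rmax, length.out = n_radii)
}

#' Ripley H-function of a point pattern in its AZ polygon
#'
#' Variance-stabilized, boundary-corrected Ripley statistic:
#' K(r) is estimated with the translation (Goreaud-Pelissier) edge correction
#' over the AZ polygon, L(r) = sqrt(K/pi), and H(r) = L(r) - r. Positive H
#' indicates clustering at scale r, negative H regularity. The default radii
#' grid is 40 evenly spaced radii up to half the square root of the AZ area.
#'
#' @param pattern a [point_pattern()] with >= 2 points.
#' @param radii_nm strictly increasing positive radii, at most half the
#'   polygon diameter.
#' @return data.frame with columns `r_nm`, `k`, `l`, `h`.
#' @export
ripley_h <- function(pattern, radii_nm = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n_points < 2L) stop("Ripley H needs >= 2 points")
  if (is.null(radii_nm)) radii_nm <- .default_radii(pattern$polygon)
  .check_radii(radii_nm, pattern$polygon)
  w <- .correction_window(pattern$polygon)
  .ripley_h_raw(pattern$points_nm, w, radii_nm)
}

.check_radii <- function(radii_nm, polygon) {
  if (any(radii_nm <= 0) || is.unsorted(radii_nm, strictly = TRUE)) {
    stop("radii must be positive and strictly increasing")
  }
  if (max(radii_nm) > .poly_diameter(polygon) / 2 + 1e-9) {
    stop("largest radius exceeds half the polygon diameter")
  }
  invisible(radii_nm)
}

.ripley_h_raw <- function(points, window_vertices, radii_nm) {
  K <- cpp_ripley_k(points[, 1L], points[, 2L], window_vertices, radii_nm)
  L <- sqrt(K / pi)
  data.frame(r_nm = radii_nm, k = K, l = L, h = L - radii_nm)
}

#' Maximum-absolute-deviation (MAD) envelope test for clustering
#'
#' Monte-Carlo goodness-of-fit test of complete spatial randomness based on
#' the H-function: the statistic is T = max_r |H(r) - mean_null H(r)|, the
#' null distribution comes from `n_sim` CSR placements of the same number of
#' points in the same polygon, and the p-value is the rank estimator
#' (1 + #\{null T >= data T\}) / (n_sim + 1). A pattern is called clustered
#' when p < 0.05 and the data H exceeds the null mean at the radius where the
#' deviation is maximal (one-sided direction check, so regular patterns are
#' not called clustered).
#'
#' @param pattern a [point_pattern()] with >= 5 points.
#' @param radii_nm radii grid; default as in [ripley_h()].
#' @param n_sim number of CSR simulations, >= 19 (default 200).
#' @param seed integer seed.
#' @return list: `mad_p`, `clustered`, `t_data`, `t_null`, `radii_nm`,
#'   `h_data`, `h_null_mean`, `h_null_sd`, `n_sim`.
#' @export
mad_test <- function(pattern, radii_nm = NULL, n_sim = 200L, seed = 1L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n_points < 5L) stop("MAD test needs >= 5 points (insufficient pattern)")
  if (n_sim < 19L) stop("n_sim must be >= 19")
  if (is.null(radii_nm)) radii_nm <- .default_radii(pattern$polygon)
  .check_radii(radii_nm, pattern$polygon)
  w <- .correction_window(pattern$polygon)
  h_data <- .ripley_h_raw(pattern$points_nm, w, radii_nm)$h
  h_null <- with_seed(seed, {
    vapply(
      seq_len(n_sim),
      function(i) {
        p <- .csr_points(pattern$polygon, pattern$n_points)
        .ripley_h_raw(p, w, radii_nm)$h
      },
      numeric(length(radii_nm))
    )
  })
  h_bar <- rowMeans(h_null)
  t_data <- max(abs(h_data - h_bar))
  t_null <- apply(abs(h_null - h_bar), 2L, max)
  p <- (1 + sum(t_null >= t_data)) / (n_sim + 1)
  imax <- which.max(abs(h_data - h_bar))
  clustered <- (p < 0.05) && (h_data[imax] > h_bar[imax])
  list(
    mad_p = p, clustered = clustered, t_data = t_data, t_null = t_null,
    radii_nm = radii_nm, h_data = h_data, h_null_mean = h_bar,
    h_null_sd = apply(h_null, 1L, sd), n_sim = as.integer(n_sim)
  )
}

#' DBSCAN clustering of gold-particle coordinates
#'
#' Density-based clustering with neighborhood radius `eps_nm` (the maximum
#' distance between two points assigned to the same cluster) and `min_pts`,
#' the minimum number of points within a single cluster. The neighborhood
#' count includes the focal point, so `min_pts = 2` means "at least one
#' neighbor within eps". Points are scanned in input order, making labels
#' deterministic; border points tied between clusters join the
#' first-discovered core cluster. Unassigned points are noise (label 0).
#'
#' @param points_nm numeric matrix with columns (x, y) in nm (0 rows allowed).
#' @param eps_nm neighborhood radius in nm, > 0.
#' @param min_pts minimum cluster size, integer >= 1.
#' @return Object of class `cluster_result`: `labels` (0 = noise),
#'   `n_clusters`, `cluster_sizes`, `centroids_nm`, `eps_nm`, `min_pts`.
#' @export
dbscan <- function(points_nm, eps_nm, min_pts = 2L) {
  if (eps_nm <= 0) stop("eps_nm must be > 0")
  if (min_pts < 1L || min_pts != round(min_pts)) stop("min_pts must be an integer >= 1")
  p <- .as_points(points_nm)
  if (nrow(p) == 0L) {
    return(structure(
      list(
        labels = integer(0), n_clusters = 0L, cluster_sizes = integer(0),
        centroids_nm = matrix(numeric(0), ncol = 2L),
        eps_nm = eps_nm, min_pts = as.integer(min_pts)
      ),
      class = "cluster_result"
    ))
  }
  labels <- cpp_dbscan(p[, 1L], p[, 2L], eps_nm, as.integer(min_pts))
  nc <- max(labels)
  sizes <- if (nc > 0L) tabulate(labels[labels > 0L], nbins = nc) else integer(0)
  centroids <- if (nc > 0L) {
    t(vapply(
      seq_len(nc),
      function(k) colMeans(p[labels == k, , drop = FALSE]),
      numeric(2L)
    ))
  } else {
    matrix(numeric(0), ncol = 2L)
  }
  structure(
    list(
      labels = labels, n_clusters = nc, cluster_sizes = sizes,
      centroids_nm = centroids, eps_nm = eps_nm, min_pts = as.integer(min_pts)
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster_result: %d clusters (eps = %g nm, MinPts = %d), %d noise points\n",
    x$n_clusters, x$eps_nm, x$min_pts, sum(x$labels == 0L)
  ))
  invisible(x)
}

#' Select the DBSCAN radius by sweeping eps against CSR nulls
#'
#' For each integer eps in `eps_range_nm` the mean DBSCAN cluster count over
#' the AZ patterns is compared with the mean over CSR replicates matched in
#' point count and polygon; `eps_star` is the eps maximizing the absolute
#' difference (ties broken toward the smaller eps). A flat-profile flag is
#' raised when the maximal differential is below 0.5 clusters, as for CSR
#' input populations.
#'
#' @param patterns list of [point_pattern()] objects (>= 1 with >= 2 points).
#' @param eps_range_nm integer range of eps values, default c(1, 100).
#' @param min_pts DBSCAN MinPts, default 2.
#' @param n_null CSR replicates per AZ, default 20.
#' @param seed integer seed.
#' @return list: `eps_star`, `flat_profile`, `max_diff`, and `profile`
#'   (data.frame eps_nm, mean_nc_data, mean_nc_null, abs_diff).
#' @export
eps_sweep <- function(patterns, eps_range_nm = c(1L, 100L), min_pts = 2L,
                      n_null = 20L, seed = 1L) {
  if (inherits(patterns, "point_pattern")) patterns <- list(patterns)
  if (!length(patterns) || !any(vapply(patterns, function(p) p$n_points, 0L) >= 2L)) {
    stop("need at least one pattern with >= 2 points")
  }
  eps_grid <- seq(as.integer(eps_range_nm[1L]), as.integer(eps_range_nm[2L]))
  null_sets <- with_seed(seed, {
    lapply(patterns, function(p) {
      lapply(seq_len(n_null), function(i) .csr_points(p$polygon, p$n_points))
    })
  })
  nc_of <- function(pts, eps) {
    if (nrow(pts) == 0L) return(0L)
    max(cpp_dbscan(pts[, 1L], pts[, 2L], eps, as.integer(min_pts)))
  }
  mean_nc_data <- vapply(eps_grid, function(eps) {
    mean(vapply(patterns, function(p) nc_of(p$points_nm, eps), 0L))
  }, numeric(1L))
  mean_nc_null <- vapply(eps_grid, function(eps) {
    mean(vapply(null_sets, function(reps) {
      mean(vapply(reps, function(pts) nc_of(pts, eps), 0L))
    }, numeric(1L)))
  }, numeric(1L))
  diffs <- abs(mean_nc_data - mean_nc_null)
  i_star <- which.max(diffs)  # which.max takes the first (smallest eps) on ties
  list(
    eps_star = eps_grid[i_star],
    flat_profile = diffs[i_star] < 0.5,
    max_diff = diffs[i_star],
    profile = data.frame(
      eps_nm = eps_grid, mean_nc_data = mean_nc_data,
      mean_nc_null = mean_nc_null, abs_diff = diffs
    )
  )
}

#' Summary metrics of a DBSCAN clustering within an AZ
#'
#' Cluster density (clusters per um^2 of AZ area), particles per cluster, and
#' the nearest-neighbor inter-cluster (centroid) distance. The inter-cluster
#' NND is undefined (NA, flagged) with fewer than 2 clusters.
#'
#' @param result a [dbscan()] `cluster_result`.
#' @param polygon the [az_polygon()] of the AZ.
#' @return list: `n_clusters`, `cluster_density_per_um2`,
#'   `particles_per_cluster`, `mean_particles_per_cluster`,
#'   `intercluster_nnd_nm` (per cluster), `mean_intercluster_nnd_nm`,
#'   `intercluster_defined`.
#' @export
cluster_metrics <- function(result, polygon) {
  stopifnot(inherits(result, "cluster_result"), inherits(polygon, "az_polygon"))
  nc <- result$n_clusters
  dens <- nc / polygon$area_um2
  if (nc >= 2L) {
    d <- as.matrix(stats::dist(result$centroids_nm))
    diag(d) <- Inf
    icd <- unname(apply(d, 1L, min))
    defined <- TRUE
  } else {
    icd <- rep(NA_real_, nc)
    defined <- FALSE
  }
  list(
    n_clusters = nc,
    cluster_density_per_um2 = dens,
    particles_per_cluster = result$cluster_sizes,
    mean_particles_per_cluster = if (nc > 0L) mean(result$cluster_sizes) else NA_real_,
    intercluster_nnd_nm = icd,
    mean_intercluster_nnd_nm = if (defined) mean(icd) else NA_real_,
    intercluster_defined = defined
  )
}

#' Gold-particle density of an AZ
#'
#' Point count divided by the polygon area in um^2 (used both for specific
#' AZ labeling and for nonspecific background on surrounding membranes).
#'
#' @param pattern a [point_pattern()].
#' @return density in particles per um^2.
#' @export
gold_density <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$polygon$area_um2 <= 0) stop("polygon area is zero")
  pattern$n_points / pattern$polygon$area_um2
}
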