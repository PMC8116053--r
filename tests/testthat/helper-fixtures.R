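# Shared fixtures and independent oracles used across test files.

# axis-aligned square window, side in nm, lower-left at the origin
unit_square_nm <- function(side = 1000) {
  az_polygon(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

# exact (mu, var) points on the MPFA parabola var = q*mu - mu^2/N
analytic_mv <- function(n_sites, q_pA, pv, n_sweeps = 30L) {
  mu <- n_sites * q_pA * pv
  data.frame(
    pulse = seq_along(pv), mu_pA = mu,
    var_pA2 = n_sites * q_pA^2 * pv * (1 - pv),
    n_sweeps = n_sweeps
  )
}

# Brute-force oracle for DBSCAN at MinPts = 2: clusters are the connected
# components (of size >= 2) of the eps-distance graph. Plain BFS, independent
# of the package's implementation.
brute_components <- function(points, eps) {
  n <- nrow(points)
  if (n == 0L) return(list(n_clusters = 0L, sizes = integer(0)))
  d <- as.matrix(stats::dist(points))
  adj <- d <= eps
  diag(adj) <- FALSE
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  keep <- sizes >= 2L
  list(n_clusters = sum(keep), sizes = sort(sizes[keep]))
}

# manual step-down Holm adjustment, an oracle independent of stats::p.adjust
holm_manual <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, (n - seq_len(n) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(n)
  out[o] <- adj
  out
}
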