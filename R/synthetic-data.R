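#' Ground-truth quantal parameters of a connection
#'
#' The generative model behind the simulated paired recordings: a connection
#' has `n_sites` independent release sites (N), each releasing at most one
#' vesicle per action potential with per-pulse vesicular release probability
#' Pv, and each released vesicle contributing a quantal current of `q_pA`
#' (optionally jittered with intra-site CV `cv_q`). Additive Gaussian baseline
#' noise models the measurement.
#'
#' @param n_sites integer >= 1, number of functional release sites (N).
#' @param q_pA quantal size in pA, > 0.
#' @param pv_per_pulse numeric vector of per-pulse release probabilities in
#'   \[0, 1\] (e.g. 6 pulses of a 40 Hz train).
#' @param cv_q intra-site quantal coefficient of variation, >= 0.
#' @param noise_sd_pA additive measurement noise SD in pA, >= 0.
#' @return Object of class `quantal_ground_truth`.
#' @export
quantal_ground_truth <- function(n_sites, q_pA, pv_per_pulse,
                                 cv_q = 0, noise_sd_pA = 0) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1 ||
      n_sites != round(n_sites)) {
    stop("n_sites must be a single integer >= 1")
  }
  if (!is.numeric(q_pA) || length(q_pA) != 1L || q_pA <= 0) {
    stop("q_pA must be a single positive number")
  }
  if (!is.numeric(pv_per_pulse) || length(pv_per_pulse) < 1L ||
      any(pv_per_pulse < 0 | pv_per_pulse > 1)) {
    stop("pv_per_pulse must be probabilities in [0, 1]")
  }
  if (!is.numeric(cv_q) || cv_q < 0) stop("cv_q must be >= 0")
  if (!is.numeric(noise_sd_pA) || noise_sd_pA < 0) stop("noise_sd_pA must be >= 0")
  structure(
    list(
      n_sites = as.integer(n_sites), q_pA = q_pA,
      pv_per_pulse = as.numeric(pv_per_pulse),
      cv_q = cv_q, noise_sd_pA = noise_sd_pA
    ),
    class = "quantal_ground_truth"
  )
}

#' EPSC sweep matrix
#'
#' Peak amplitudes of unitary EPSCs, rows = sweeps, columns = pulse positions
#' within the train.
#'
#' @param amplitudes_pA numeric matrix of peak amplitudes in pA.
#' @param baseline_corrected logical; whether amplitudes have been corrected
#'   with the baseline negative peak.
#' @return Object of class `sweep_matrix`.
#' @export
sweep_matrix <- function(amplitudes_pA, baseline_corrected = FALSE) {
  a <- as.matrix(amplitudes_pA)
  if (!is.numeric(a) || anyNA(a)) stop("amplitudes must be numeric with no missing entries")
  if (nrow(a) < 1L || ncol(a) < 1L) stop("need at least one sweep and one pulse")
  structure(
    list(
      amplitudes_pA = unname(a),
      n_sweeps = nrow(a), n_pulses = ncol(a),
      baseline_corrected = isTRUE(baseline_corrected)
    ),
    class = "sweep_matrix"
  )
}

#' @export
print.sweep_matrix <- function(x, ...) {
  cat(sprintf(
    "sweep_matrix: %d sweeps x %d pulses (%sbaseline corrected)\n",
    x$n_sweeps, x$n_pulses, if (x$baseline_corrected) "" else "not "
  ))
  invisible(x)
}

#' Simulate quantal EPSC sweeps
#'
#' Draws peak amplitudes under the binomial release model MPFA assumes: at
#' pulse i, the number of released vesicles is Binomial(N, Pv_i), each vesicle
#' contributes q (jittered by `cv_q`), and Gaussian baseline noise is added.
#' By default pulse positions are independent conditions (no depletion
#' coupling); an optional depletion mode makes a site that released
#' unavailable until it recovers with time constant `recovery_tau_ms`.
#'
#' @param truth a [quantal_ground_truth()].
#' @param n_sweeps number of sweeps to simulate, >= 1.
#' @param seed integer seed; the same seed reproduces the matrix bit-for-bit.
#' @param depletion logical, default `FALSE` (pulses independent).
#' @param recovery_tau_ms recovery time constant of a depleted site (ms), used
#'   only when `depletion = TRUE`.
#' @param isi_ms inter-stimulus interval in ms (25 ms for a 40 Hz train).
#' @return A [sweep_matrix()] with `baseline_corrected = TRUE` (the generator
#'   emits clean peak amplitudes).
#' @examples
#' truth <- quantal_ground_truth(10, 30, c(0.8, 0.65, 0.5, 0.4, 0.3, 0.2),
#'                               cv_q = 0, noise_sd_pA = 2)
#' sw <- gen_quantal_sweeps(truth, n_sweeps = 30, seed = 1)
#' colMeans(sw$amplitudes_pA)
#' @export
gen_quantal_sweeps <- function(truth, n_sweeps, seed, depletion = FALSE,
                               recovery_tau_ms = 50, isi_ms = 25) {
  stopifnot(inherits(truth, "quantal_ground_truth"))
  if (!is.numeric(n_sweeps) || length(n_sweeps) != 1L || n_sweeps < 1) {
    stop("n_sweeps must be >= 1")
  }
  n_sweeps <- as.integer(n_sweeps)
  n_pulses <- length(truth$pv_per_pulse)
  amp <- with_seed(seed, {
    if (!depletion) {
      m <- matrix(0, n_sweeps, n_pulses)
      for (i in seq_len(n_pulses)) {
        k <- rbinom(n_sweeps, truth$n_sites, truth$pv_per_pulse[i])
        a <- truth$q_pA * k
        if (truth$cv_q > 0) {
          a <- a + truth$q_pA * truth$cv_q * sqrt(k) * rnorm(n_sweeps)
        }
        m[, i] <- a
      }
      m
    } else {
      p_rec <- 1 - exp(-isi_ms / recovery_tau_ms)
      m <- matrix(0, n_sweeps, n_pulses)
      for (s in seq_len(n_sweeps)) {
        avail <- rep(TRUE, truth$n_sites)
        for (i in seq_len(n_pulses)) {
          if (i > 1L) {
            rec <- !avail & (runif(truth$n_sites) < p_rec)
            avail[rec] <- TRUE
          }
          rel <- avail & (runif(truth$n_sites) < truth$pv_per_pulse[i])
          k <- sum(rel)
          a <- truth$q_pA * k
          if (truth$cv_q > 0 && k > 0) {
            a <- a + truth$q_pA * truth$cv_q * sqrt(k) * rnorm(1L)
          }
          m[s, i] <- a
          avail[rel] <- FALSE
        }
      }
      m
    }
    if (truth$noise_sd_pA > 0) {
      m <- m + matrix(
        rnorm(n_sweeps * n_pulses, 0, truth$noise_sd_pA), n_sweeps, n_pulses
      )
    }
    m
  })
  sweep_matrix(amp, baseline_corrected = TRUE)
}

#' Generate a random active-zone polygon of given area
#'
#' Builds a star polygon around the origin (angles jittered, radii jittered by
#' `irregularity`) and rescales it so the shoelace area matches `area_um2`
#' exactly. `irregularity = 0` gives the regular n-gon. The default area is
#' the measured mean AZ area of the modeled synapse type (0.071 um^2).
#'
#' @param area_um2 target area in um^2, > 0.
#' @param n_vertices number of vertices, >= 3.
#' @param irregularity in \[0, 1): relative jitter of vertex angles and radii.
#' @param seed integer seed.
#' @return An [az_polygon()] with `area_um2` equal to the target (rel. tol 1e-9).
#' @export
gen_az_polygon <- function(area_um2 = 0.071, n_vertices = 8L, irregularity = 0,
                           seed = 1L) {
  if (!is.numeric(area_um2) || area_um2 <= 0) stop("area_um2 must be > 0")
  if (n_vertices < 3L) stop("n_vertices must be >= 3")
  if (irregularity < 0 || irregularity >= 1) stop("irregularity must be in [0, 1)")
  n <- as.integer(n_vertices)
  v <- with_seed(seed, {
    gaps <- 1 + irregularity * runif(n, -1, 1)
    ang <- 2 * pi * (cumsum(gaps) - gaps[1L]) / sum(gaps)
    rad <- 1 + irregularity * runif(n, -1, 1)
    cbind(rad * cos(ang), rad * sin(ang))
  })
  raw <- abs(.signed_area(v))
  scale <- sqrt(area_um2 * NM2_PER_UM2 / raw)
  az_polygon(v * scale)
}

# Uniform (CSR) points inside a polygon by rejection from the bounding box.
.csr_points <- function(polygon, n, max_reject = 1e6) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  v <- polygon$vertices_nm
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  rejected <- 0
  while (got < n) {
    m <- max(2L * (n - got), 32L)
    cand <- cbind(runif(m, xr[1L], xr[2L]), runif(m, yr[1L], yr[2L]))
    keep <- point_in_polygon(cand, polygon)
    rejected <- rejected + sum(!keep)
    if (rejected > max_reject) stop("rejection sampling guard exceeded (1e6 rejections)")
    k <- which(keep)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      out[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

#' Generate a CSR or clustered point pattern inside an AZ polygon
#'
#' CSR ("complete spatial randomness") places points uniformly in the polygon
#' by rejection sampling. Clustered mode places `n_clusters` cluster centers
#' uniformly, assigns each point to a random center and draws it from an
#' isotropic Gaussian of SD `sigma_nm`; points falling outside the polygon are
#' resampled (not clipped), preserving within-cluster isotropy.
#'
#' @param polygon an [az_polygon()].
#' @param mode `"CSR"` or `"clustered"`.
#' @param n_points number of points, >= 0.
#' @param n_clusters number of cluster centers (clustered mode), >= 1.
#' @param sigma_nm within-cluster Gaussian SD in nm, >= 0.
#' @param seed integer seed.
#' @param az_id identifier for the returned pattern.
#' @return A [point_pattern()] with exactly `n_points` points.
#' @export
gen_point_pattern <- function(polygon, mode = c("CSR", "clustered"), n_points,
                              n_clusters = NULL, sigma_nm = NULL, seed = 1L,
                              az_id = "AZ1") {
  stopifnot(inherits(polygon, "az_polygon"))
  mode <- match.arg(mode)
  if (!is.numeric(n_points) || n_points < 0) stop("n_points must be >= 0")
  n_points <- as.integer(n_points)
  pts <- with_seed(seed, {
    if (mode == "CSR") {
      .csr_points(polygon, n_points)
    } else {
      if (is.null(n_clusters) || n_clusters < 1) stop("clustered mode requires n_clusters >= 1")
      if (is.null(sigma_nm) || sigma_nm < 0) stop("clustered mode requires sigma_nm >= 0")
      centers <- .csr_points(polygon, as.integer(n_clusters))
      if (n_points == 0L) {
        matrix(numeric(0), ncol = 2L)
      } else {
        assign <- sample.int(nrow(centers), n_points, replace = TRUE)
        out <- matrix(NA_real_, n_points, 2L)
        todo <- seq_len(n_points)
        rejected <- 0
        while (length(todo)) {
          cand <- centers[assign[todo], , drop = FALSE] +
            matrix(rnorm(2L * length(todo), 0, sigma_nm), ncol = 2L)
          keep <- point_in_polygon(cand, polygon)
          rejected <- rejected + sum(!keep)
          if (rejected > 1e6) stop("rejection sampling guard exceeded (1e6 rejections)")
          out[todo[keep], ] <- cand[keep, , drop = FALSE]
          todo <- todo[!keep]
        }
        out
      }
    }
  })
  point_pattern(pts, polygon, az_id = az_id)
}

#' Binomial thinning of a point pattern (antibody labeling model)
#'
#' Each point (epitope) is retained independently with probability `p`,
#' emulating immunogold labeling where antibody binding approximates a
#' binomial process. The polygon is unchanged.
#'
#' @param pattern a [point_pattern()].
#' @param p retention (labeling) probability in \[0, 1\].
#' @param seed integer seed.
#' @return A thinned [point_pattern()].
#' @export
thin_labeling <- function(pattern, p, seed = 1L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop("p must be a probability in [0, 1]")
  }
  keep <- with_seed(seed, runif(pattern$n_points) < p)
  point_pattern(
    pattern$points_nm[keep, , drop = FALSE], pattern$polygon,
    az_id = pattern$az_id
  )
}

# Lognormal draws parameterized by arithmetic mean and CV; cv = 0 degenerates
# to the constant mean.
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic synapse population for intensity analysis
#'
#' Emulates per-synapse integrated fluorescence intensities: synapse areas are
#' lognormal; the PSD-95 signal is exactly proportional to area (size proxy
#' with virtually no size-independent variability); the Munc13-1 signal is
#' proportional to area times an extra lognormal density factor with CV
#' `munc13_density_cv`, producing size-independent variability in the priming
#' protein. Defaults are the measured population values of the modeled
#' synapses (area 0.071 um^2 with CV 0.43; densities 497 and 383 with
#' Munc13-1 density CV 0.33).
#'
#' @param n number of synapses, >= 1.
#' @param area_mean_um2 arithmetic mean synapse (AZ) area in um^2.
#' @param area_cv CV of the area distribution (lognormal), >= 0.
#' @param psd95_density PSD-95 intensity per um^2 (arbitrary units), > 0.
#' @param munc13_density_mean mean Munc13-1 intensity per um^2, > 0.
#' @param munc13_density_cv lognormal CV of the Munc13-1 density, >= 0.
#' @param seed integer seed.
#' @return data.frame with columns `synapse_id`, `area_um2`, `psd95_intensity`,
#'   `munc13_intensity`.
#' @export
gen_synapse_population <- function(n, area_mean_um2 = 0.071, area_cv = 0.43,
                                   psd95_density = 497,
                                   munc13_density_mean = 383,
                                   munc13_density_cv = 0.33, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (area_mean_um2 <= 0 || psd95_density <= 0 || munc13_density_mean <= 0) {
    stop("means and densities must be positive")
  }
  if (area_cv < 0 || munc13_density_cv < 0) stop("CVs must be >= 0")
  n <- as.integer(n)
  with_seed(seed, {
    area <- .rlnorm_mean_cv(n, area_mean_um2, area_cv)
    dens <- munc13_density_mean * .rlnorm_mean_cv(n, 1, munc13_density_cv)
    data.frame(
      synapse_id = sprintf("syn%04d", seq_len(n)),
      area_um2 = area,
      psd95_intensity = psd95_density * area,
      munc13_intensity = dens * area
    )
  })
}
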