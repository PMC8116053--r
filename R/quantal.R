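#' Baseline-correct raw EPSC peak amplitudes
#'
#' Measured peak amplitudes are corrected with the amplitude of the baseline
#' negative peak, element-wise: corrected = raw - baseline.
#'
#' @param raw_amplitudes_pA numeric matrix, sweeps x pulses, in pA.
#' @param baselines_pA numeric matrix of the same shape.
#' @return A [sweep_matrix()] with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(raw_amplitudes_pA, baselines_pA) {
  raw <- as.matrix(raw_amplitudes_pA)
  b <- as.matrix(baselines_pA)
  if (!identical(dim(raw), dim(b))) stop("raw and baseline matrices differ in shape")
  sweep_matrix(raw - b, baseline_corrected = TRUE)
}

#' Subselect pairs by mean EPSC rise time
#'
#' Restricts analysis to presumed perisomatic synapses by keeping pairs whose
#' mean 10-90% rise time is at or below the threshold (default 0.5 ms, i.e.
#' 500 us; the boundary is inclusive).
#'
#' @param records data.frame with columns `pair_id` and `mean_rt_ms`.
#' @param threshold_ms inclusive rise-time threshold in ms.
#' @return character/original vector of pair ids passing the filter.
#' @export
rise_time_filter <- function(records, threshold_ms = 0.5) {
  stopifnot(is.data.frame(records), all(c("pair_id", "mean_rt_ms") %in% names(records)))
  if (nrow(records) == 0L) return(records$pair_id)
  if (any(records$mean_rt_ms < 0)) stop("negative rise time")
  records$pair_id[records$mean_rt_ms <= threshold_ms]
}

#' Paired-pulse ratio (EPSC2/EPSC1)
#'
#' @param sweeps a [sweep_matrix()] with at least two pulse positions.
#' @return mean amplitude at pulse 2 divided by mean amplitude at pulse 1.
#' @export
paired_pulse_ratio <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_matrix"))
  if (sweeps$n_pulses < 2L) stop("paired-pulse ratio needs >= 2 pulses")
  m <- colMeans(sweeps$amplitudes_pA)
  if (m[1L] == 0) stop("mean amplitude of pulse 1 is zero")
  unname(m[2L] / m[1L])
}

#' Per-pulse mean and variance of EPSC peak amplitudes
#'
#' Computes, for each pulse position, the sample mean and the unbiased (n-1)
#' sample variance across sweeps: the input points of the MPFA parabola.
#' Recordings with fewer than `min_sweeps` sweeps (24 in the source protocol)
#' are flagged with a warning rather than dropped.
#'
#' @param sweeps a [sweep_matrix()] with >= 2 sweeps.
#' @param min_sweeps sweep count below which a warning is emitted.
#' @return data.frame of class `mean_variance` with columns `pulse`, `mu_pA`,
#'   `var_pA2`, `n_sweeps` and attribute `low_sweeps`.
#' @export
mean_variance <- function(sweeps, min_sweeps = 24L) {
  stopifnot(inherits(sweeps, "sweep_matrix"))
  if (sweeps$n_sweeps < 2L) stop("variance needs >= 2 sweeps")
  a <- sweeps$amplitudes_pA
  out <- data.frame(
    pulse = seq_len(sweeps$n_pulses),
    mu_pA = colMeans(a),
    var_pA2 = apply(a, 2L, var),
    n_sweeps = sweeps$n_sweeps
  )
  low <- sweeps$n_sweeps < min_sweeps
  if (low) {
    warning(sprintf(
      "only %d sweeps (< %d): mean-variance points may be unreliable",
      sweeps$n_sweeps, min_sweeps
    ))
  }
  attr(out, "low_sweeps") <- low
  class(out) <- c("mean_variance", "data.frame")
  out
}

.check_mv <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("mu_pA", "var_pA2") %in% names(points))) {
    stop("points must be a data.frame with columns mu_pA and var_pA2")
  }
  points
}

#' Quality-control exclusion rule for MPFA
#'
#' A recording is excluded when the pulse with the largest mean amplitude also
#' has the largest variance: in that case all points lie on the rising limb of
#' the parabola, the maximal Pv likely never exceeded 0.5, and N is poorly
#' constrained. Ties on the mean are broken toward the larger variance (i.e.
#' toward exclusion).
#'
#' @param points a [mean_variance()] data.frame (>= 2 distinct mean values).
#' @return `TRUE` if the recording should be excluded.
#' @export
qc_exclude <- function(points) {
  points <- .check_mv(points)
  mu <- points$mu_pA; v <- points$var_pA2
  if (length(mu) < 2L || length(unique(mu)) < 2L) {
    stop("qc_exclude needs >= 2 points with distinct mean values")
  }
  v_at_max_mu <- max(v[mu == max(mu)])
  v_at_max_mu >= max(v)
}

#' Fit the MPFA parabola to mean-variance points
#'
#' Least-squares fit of the through-origin parabola
#' \deqn{\sigma^2 = q\,\mu - \mu^2/N,}{var = q*mu - mu^2/N,}
#' parameterized as `var = a*mu + b*mu^2` with the physical constraints
#' `a > 0` (quantal size) and `b < 0` (finite N). Estimates are
#' `q_hat = a` and `n_hat = -1/b`; per-pulse release probabilities follow as
#' `pv_i = mu_i / (n_hat * q_hat)` and `pv1` is the first-pulse Pv. When the
#' fitted curvature is non-negative (pure line: the Pv -> 0 limit, N
#' unidentifiable) a typed fit-failure result is returned rather than an
#' error, so batch pipelines continue.
#'
#' @param points a [mean_variance()] data.frame with >= 3 points.
#' @param weighting `"none"` (default; the source analysis names no weighting)
#'   or `"inverse_variance"`, which weights each point by
#'   (n-1)/(2 var^2), the reciprocal of Var\[s^2\] under normality, for
#'   sensitivity analysis.
#' @return Object of class `quantal_fit`: `fit_ok`, `n_hat`, `q_hat_pA`,
#'   `pv_per_pulse`, `pv1`, `rss`, `qc_excluded`, `n_points`, `pv_overshoot`,
#'   `reason` (on failure).
#' @examples
#' pts <- data.frame(mu_pA = c(60, 150, 240), var_pA2 = c(1440, 2250, 1440),
#'                   n_sweeps = 30)
#' fit <- mpfa_fit(pts)
#' c(fit$n_hat, fit$q_hat_pA)  # 10, 30
#' @export
mpfa_fit <- function(points, weighting = c("none", "inverse_variance")) {
  points <- .check_mv(points)
  weighting <- match.arg(weighting)
  mu <- points$mu_pA
  v <- points$var_pA2
  if (length(mu) < 3L) stop("MPFA needs >= 3 mean-variance points")
  qc <- tryCatch(qc_exclude(points), error = function(e) NA)
  w <- if (weighting == "none") {
    rep(1, length(mu))
  } else {
    nsw <- if ("n_sweeps" %in% names(points)) points$n_sweeps else rep(30L, length(mu))
    (nsw - 1) / (2 * pmax(v, .Machine$double.eps)^2)
  }
  X <- cbind(mu, mu^2)
  fit <- stats::lm.wfit(X, v, w)
  a <- unname(fit$coefficients[1L])
  b <- unname(fit$coefficients[2L])
  # curvature indistinguishable from zero (or wrong-signed) => N unidentifiable
  curv_tol <- 1e-10 * max(abs(a), .Machine$double.eps) / max(abs(mu))
  failed <- !is.finite(a) || !is.finite(b) || a <= 0 || b >= -curv_tol
  base <- list(
    n_points = length(mu), qc_excluded = isTRUE(qc),
    coef_a = a, coef_b = b
  )
  if (failed) {
    out <- c(base, list(
      fit_ok = FALSE, n_hat = NA_real_, q_hat_pA = NA_real_,
      pv_per_pulse = rep(NA_real_, length(mu)), pv1 = NA_real_,
      rss = sum((v - X %*% ifelse(is.finite(c(a, b)), c(a, b), 0))^2),
      pv_overshoot = FALSE,
      reason = "no negative curvature: variance-mean relation is linear (N unidentifiable, Pv likely << 0.5)"
    ))
  } else {
    n_hat <- -1 / b
    q_hat <- a
    pv <- mu / (n_hat * q_hat)
    overshoot <- any(pv > 1)
    if (any(pv > 1.05)) {
      warning("fitted Pv exceeds 1.05 for at least one pulse; fit is suspect")
    }
    out <- c(base, list(
      fit_ok = TRUE, n_hat = n_hat, q_hat_pA = q_hat,
      pv_per_pulse = pv, pv1 = pv[1L],
      rss = sum((v - X %*% c(a, b))^2),
      pv_overshoot = overshoot, reason = NA_character_
    ))
  }
  structure(out, class = "quantal_fit")
}

#' @export
print.quantal_fit <- function(x, ...) {
  if (!x$fit_ok) {
    cat("quantal_fit: FAILED -", x$reason, "\n")
  } else {
    cat(sprintf(
      "quantal_fit: N = %.2f, q = %.2f pA, Pv1 = %.3f (%d points%s)\n",
      x$n_hat, x$q_hat_pA, x$pv1, x$n_points,
      if (x$qc_excluded) ", QC-EXCLUDED" else ""
    ))
  }
  invisible(x)
}

#' Vesicular release probability from fitted quantal parameters
#'
#' Pv = P1 / (N * q), with P1 the peak amplitude of the first EPSC.
#'
#' @param p1_pA first-pulse peak amplitude in pA.
#' @param n_hat estimated number of release sites, > 0.
#' @param q_hat_pA estimated quantal size in pA, > 0.
#' @return Pv (dimensionless).
#' @export
pv_from_fit <- function(p1_pA, n_hat, q_hat_pA) {
  if (!is.finite(n_hat) || !is.finite(q_hat_pA) || n_hat <= 0 || q_hat_pA <= 0) {
    stop("n_hat and q_hat_pA must be positive")
  }
  p1_pA / (n_hat * q_hat_pA)
}

#' Rescale Pv between calcium conditions by the amplitude ratio
#'
#' Pv estimated at high \[Ca2+\] is carried to the low-\[Ca2+\] condition
#' assuming the change in extracellular calcium only affects Pv:
#' `pv_low = pv_high * amp_low / amp_high`, clipped to \[0, 1\] (with a
#' warning and a `clipped` attribute when clipping occurred).
#'
#' @param pv_high Pv in the high-\[Ca2+\] condition, in (0, 1\].
#' @param amp_low_pA,amp_high_pA mean uEPSC amplitudes in the two conditions.
#' @return Pv in the low-\[Ca2+\] condition.
#' @export
rescale_pv <- function(pv_high, amp_low_pA, amp_high_pA) {
  if (amp_low_pA <= 0 || amp_high_pA <= 0) stop("amplitudes must be positive")
  if (pv_high <= 0 || pv_high > 1) stop("pv_high must be in (0, 1]")
  out <- pv_high * amp_low_pA / amp_high_pA
  clipped <- out > 1
  if (clipped) {
    warning("rescaled Pv exceeded 1; clipped")
    out <- 1
  }
  attr(out, "clipped") <- clipped
  out
}

#' Relative contributions of N, q and Pv to amplitude variance
#'
#' Across a population of connections, the share of the EPSC amplitude
#' variance attributable to each quantal parameter is taken as its squared
#' coefficient of variation over the sum of the three squared CVs (amplitude
#' = N*q*Pv, so log-variances add to first order).
#'
#' @param cv_n,cv_q,cv_pv population CVs of N, q and Pv (>= 0, not all zero).
#' @return Object of class `variance_contribution` with fields `cv_n`, `cv_q`,
#'   `cv_pv`, `fraction_n`, `fraction_q`, `fraction_pv` (fractions sum to 1).
#' @export
variance_contributions <- function(cv_n, cv_q, cv_pv) {
  cvs <- c(cv_n, cv_q, cv_pv)
  if (any(!is.finite(cvs)) || any(cvs < 0)) stop("CVs must be finite and >= 0")
  tot <- sum(cvs^2)
  if (tot == 0) stop("all CVs are zero: contributions undefined")
  f <- cvs^2 / tot
  structure(
    list(
      cv_n = cv_n, cv_q = cv_q, cv_pv = cv_pv,
      fraction_n = f[1L], fraction_q = f[2L], fraction_pv = f[3L]
    ),
    class = "variance_contribution"
  )
}

#' Allocate release sites across the synapses of a multi-contact connection
#'
#' A connection verified to have k anatomical contacts receives an integer
#' split of its fitted N across the synapses, proportional to their sizes as
#' assessed from PSD-95 immunoreaction intensities. Every contact gets at
#' least one site; the split follows the largest-remainder method on the
#' full-N quotas, with remainder ties broken toward the larger intensity and
#' then the lower index. The allocation sums exactly to `n_total`.
#'
#' @param n_total total number of release sites (>= number of synapses).
#' @param psd95_intensities positive per-synapse PSD-95 intensities.
#' @return integer vector of per-synapse site counts.
#' @export
allocate_n <- function(n_total, psd95_intensities) {
  w <- as.numeric(psd95_intensities)
  k <- length(w)
  if (k < 1L || any(w <= 0)) stop("psd95_intensities must be positive")
  if (n_total != round(n_total) || n_total < k) {
    stop("n_total must be an integer >= number of synapses")
  }
  n_total <- as.integer(n_total)
  quota <- n_total * w / sum(w)
  alloc <- pmax(floor(quota), 1)
  rem <- quota - floor(quota)
  # distribute (or reclaim) the difference by largest (smallest) remainder
  ord <- order(-rem, -w, seq_len(k))
  left <- n_total - sum(alloc)
  i <- 1L
  while (left > 0L) {
    alloc[ord[i]] <- alloc[ord[i]] + 1L
    left <- left - 1L
    i <- if (i == k) 1L else i + 1L
  }
  ord_rev <- order(rem, w, -seq_len(k))
  i <- 1L
  while (left < 0L) {
    j <- ord_rev[i]
    if (alloc[j] > 1L) {
      alloc[j] <- alloc[j] - 1L
      left <- left + 1L
    }
    i <- if (i == k) 1L else i + 1L
  }
  as.integer(alloc)
}

#' Release probabilities of a multi-site active zone
#'
#' For an AZ with `n` independent release sites of per-site probability `pv`:
#' the probability that at least one vesicle is released is
#' `p_r = 1 - (1-pv)^n`, and the probability of multivesicular release (two
#' or more vesicles) is `p_mvr = 1 - (1-pv)^n - n*pv*(1-pv)^(n-1)`.
#'
#' @param pv vesicular release probability in \[0, 1\].
#' @param n number of release sites, integer >= 1.
#' @return list with elements `p_r` and `p_mvr`.
#' @examples
#' release_probabilities(0.4, 5)  # p_r ~ 0.92, p_mvr ~ 0.66 ("around 70%")
#' @export
release_probabilities <- function(pv, n) {
  if (pv < 0 || pv > 1) stop("pv must be in [0, 1]")
  if (n < 1 || n != round(n)) stop("n must be an integer >= 1")
  p_r <- 1 - (1 - pv)^n
  p_mvr <- p_r - n * pv * (1 - pv)^(n - 1)
  list(p_r = p_r, p_mvr = p_mvr)
}
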