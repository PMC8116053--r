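test_that("baseline correction is element-wise raw minus baseline", {
  out <- baseline_correct(matrix(100), matrix(0))
  expect_equal(out$amplitudes_pA, matrix(100))
  expect_true(out$baseline_corrected)
  expect_equal(baseline_correct(matrix(100), matrix(5))$amplitudes_pA, matrix(95))
  # sign convention: all-zero raw gives minus the baseline
  b <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(baseline_correct(matrix(0, 2, 2), b)$amplitudes_pA, -b)
  expect_error(baseline_correct(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("rise-time subselection keeps pairs at or below the threshold", {
  rec <- data.frame(pair_id = c("a", "b", "c"), mean_rt_ms = c(0.4, 0.6, 0.5))
  expect_identical(rise_time_filter(rec, 0.5), c("a", "c"))
  expect_length(rise_time_filter(rec[0, ], 0.5), 0L)
  expect_identical(rise_time_filter(rec, Inf), c("a", "b", "c"))
  expect_error(rise_time_filter(data.frame(pair_id = "a", mean_rt_ms = -1)),
               "negative")
})

test_that("paired-pulse ratio is mean(EPSC2)/mean(EPSC1)", {
  same <- sweep_matrix(matrix(c(3, 5, 3, 5), 2))
  expect_equal(paired_pulse_ratio(same), 1)
  sw <- sweep_matrix(cbind(c(90, 110), c(48, 68)))
  expect_equal(paired_pulse_ratio(sw), 0.58)
  # a facilitating pair like the exemplar recording
  fac <- sweep_matrix(cbind(c(60, 76), c(66.4, 76.4)))
  expect_equal(paired_pulse_ratio(fac), 1.05)
  expect_error(paired_pulse_ratio(sweep_matrix(cbind(c(-1, 1), c(2, 2)))), "zero")
  expect_error(paired_pulse_ratio(sweep_matrix(matrix(1, 2, 1))), "2 pulses")
})

test_that("mean_variance uses the unbiased (n-1) variance and flags low n", {
  ident <- sweep_matrix(matrix(5, 10, 3))
  mv <- suppressWarnings(mean_variance(ident))
  expect_equal(mv$var_pA2, rep(0, 3))
  two <- suppressWarnings(mean_variance(sweep_matrix(matrix(c(0, 2), 2, 1))))
  expect_equal(two$mu_pA, 1)
  expect_equal(two$var_pA2, 2)
  expect_warning(mean_variance(sweep_matrix(matrix(rnorm(20), 10))), "sweeps")
  mv24 <- mean_variance(sweep_matrix(matrix(rnorm(48), 24)))
  expect_false(attr(mv24, "low_sweeps"))
  expect_error(mean_variance(sweep_matrix(matrix(1, 1, 2))), "2 sweeps")
})

test_that("qc_exclude fires when the largest mean has the largest variance", {
  keep <- data.frame(mu_pA = c(60, 150, 240), var_pA2 = c(1440, 2250, 1440))
  expect_false(qc_exclude(keep))
  excl <- data.frame(mu_pA = c(60, 150, 240), var_pA2 = c(100, 200, 300))
  expect_true(qc_exclude(excl))
  # tie on the mean broken toward the larger variance (=> excluded)
  tie <- data.frame(mu_pA = c(100, 240, 240), var_pA2 = c(50, 80, 120))
  expect_true(qc_exclude(tie))
  expect_error(qc_exclude(data.frame(mu_pA = c(5, 5), var_pA2 = c(1, 2))),
               "distinct")
  expect_error(qc_exclude(data.frame(mu_pA = 5, var_pA2 = 1)), "2 points")
})

test_that("MPFA recovers exact parabolic points to machine precision", {
  pts <- data.frame(mu_pA = c(60, 150, 240), var_pA2 = c(1440, 2250, 1440),
                    n_sweeps = 30)
  fit <- mpfa_fit(pts)
  expect_true(fit$fit_ok)
  expect_equal(fit$n_hat, 10, tolerance = 1e-12)
  expect_equal(fit$q_hat_pA, 30, tolerance = 1e-12)
  expect_equal(fit$pv_per_pulse, c(0.2, 0.5, 0.8), tolerance = 1e-12)
  expect_equal(fit$pv1, 0.2, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-15)
  # weighted variant is identical on exact points
  fitw <- mpfa_fit(pts, weighting = "inverse_variance")
  expect_equal(fitw$n_hat, 10, tolerance = 1e-10)
})

test_that("MPFA recovery is exact over random noiseless parameter sets", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    q <- runif(1, 5, 80)
    pv <- sort(runif(4, 0.05, 0.95))
    pv[4] <- max(pv[4], 0.6)  # at least one point past the parabola apex side
    fit <- mpfa_fit(analytic_mv(n, q, pv))
    expect_true(fit$fit_ok)
    expect_lt(abs(fit$n_hat - n) / n, 1e-6)
    expect_lt(abs(fit$q_hat_pA - q) / q, 1e-6)
  }
})

test_that("a linear mean-variance relation yields a typed fit failure", {
  line <- data.frame(mu_pA = c(30, 60, 90), var_pA2 = c(30, 60, 90) * 25,
                     n_sweeps = 30)
  fit <- mpfa_fit(line)
  expect_false(fit$fit_ok)
  expect_true(is.na(fit$n_hat))
  expect_match(fit$reason, "curvature")
  expect_error(mpfa_fit(line[1:2, ]), ">= 3")
})

test_that("MPFA parameter estimates converge with sweep count", {
  truth <- quantal_ground_truth(10, 30, c(0.8, 0.65, 0.5, 0.4, 0.3, 0.2),
                                cv_q = 0, noise_sd_pA = 2)
  fit_at <- function(n_sweeps, seed) {
    sw <- gen_quantal_sweeps(truth, n_sweeps, seed = seed)
    suppressWarnings(mpfa_fit(mean_variance(sw)))
  }
  small <- vapply(1:30, function(s) fit_at(30, s)$n_hat, numeric(1))
  big <- vapply(1:10, function(s) fit_at(3000, 100 + s)$n_hat, numeric(1))
  expect_lt(abs(median(big, na.rm = TRUE) - 10), abs(median(small, na.rm = TRUE) - 10) + 0.5)
  expect_lt(abs(median(big, na.rm = TRUE) - 10), 0.5)
  # per-pulse Pv from a 3000-sweep fit matches the generator within 3 SE
  fit <- fit_at(3000, 321)
  se_pv <- sqrt(truth$pv_per_pulse * (1 - truth$pv_per_pulse) / (10 * 3000))
  expect_true(all(abs(fit$pv_per_pulse - truth$pv_per_pulse) < 3 * se_pv + 0.05))
})

test_that("pv_from_fit implements P1/(N*q)", {
  expect_equal(pv_from_fit(150, 10, 30), 0.5)
  expect_equal(pv_from_fit(0, 10, 30), 0)
  expect_equal(pv_from_fit(216, 10, 30), 0.72)
  expect_error(pv_from_fit(150, 0, 30), "positive")
})

test_that("Pv rescaling across calcium conditions uses the amplitude ratio", {
  expect_equal(rescale_pv(0.6, 50, 100), 0.3, ignore_attr = TRUE)
  expect_equal(rescale_pv(0.72, 105, 180), 0.42, ignore_attr = TRUE)
  expect_equal(rescale_pv(1.0, 100, 100), 1.0, ignore_attr = TRUE)
  expect_warning(out <- rescale_pv(0.9, 200, 100), "clipped")
  expect_equal(out, 1, ignore_attr = TRUE)
  expect_true(attr(out, "clipped"))
  expect_error(rescale_pv(0.5, -1, 100), "positive")
})

test_that("variance contributions are CV-squared shares summing to one", {
  eq <- variance_contributions(0.3, 0.3, 0.3)
  expect_equal(c(eq$fraction_n, eq$fraction_q, eq$fraction_pv), rep(1 / 3, 3))
  vc <- variance_contributions(0.9, 0.5, 0.1)
  expect_equal(vc$fraction_n, 0.81 / 1.07, tolerance = 1e-12)
  expect_equal(vc$fraction_q, 0.25 / 1.07, tolerance = 1e-12)
  expect_equal(vc$fraction_pv, 0.01 / 1.07, tolerance = 1e-12)
  solo <- variance_contributions(1, 0, 0)
  expect_equal(solo$fraction_n, 1)
  expect_error(variance_contributions(0, 0, 0), "zero")
  # invariance under common scaling of all CVs
  a <- variance_contributions(0.4, 0.2, 0.1)
  b <- variance_contributions(4, 2, 1)
  expect_equal(a$fraction_q, b$fraction_q, tolerance = 1e-12)
  expect_equal(
    a$fraction_n + a$fraction_q + a$fraction_pv, 1, tolerance = 1e-12
  )
})

test_that("allocate_n splits sites by PSD-95 size with largest remainders", {
  expect_identical(allocate_n(4, c(1, 1)), c(2L, 2L))
  expect_identical(allocate_n(10, c(2, 1)), c(7L, 3L))
  expect_identical(allocate_n(3, c(1, 1, 1)), c(1L, 1L, 1L))
  expect_error(allocate_n(2, c(1, 1, 1)), "n_total")
  # permutation equivariance and exact total
  set.seed(4)
  for (i in 1:10) {
    w <- runif(3, 0.5, 3)
    n <- sample(3:20, 1)
    a <- allocate_n(n, w)
    expect_equal(sum(a), n)
    expect_true(all(a >= 1L))
    perm <- sample(3)
    expect_identical(allocate_n(n, w[perm]), a[perm])
  }
})

test_that("release probabilities follow the binomial AZ model", {
  one <- release_probabilities(0.5, 1)
  expect_equal(one$p_r, 0.5)
  expect_equal(one$p_mvr, 0)
  sure <- release_probabilities(1, 4)
  expect_equal(sure$p_r, 1)
  expect_equal(sure$p_mvr, 1)
  # five release sites at Pv ~ 0.4: multivesicular release around 70%
  mvr <- release_probabilities(0.4, 5)
  expect_equal(mvr$p_r, 0.92224, tolerance = 1e-12)
  expect_equal(mvr$p_mvr, 0.66304, tolerance = 1e-12)
  expect_error(release_probabilities(1.2, 5), "pv")
})
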