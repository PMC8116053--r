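#' Normalize synapse intensities to a surrounding-population mean
#'
#' Identified-synapse signals are expressed relative to the arithmetic mean of
#' a surrounding-synapse population (49-89 synapses in the source protocol;
#' smaller populations are flagged). `method = "median"` is offered as a
#' robust alternative.
#'
#' @param values raw intensities of the synapses of interest.
#' @param population raw intensities of the normalization population
#'   (non-empty, positive mean).
#' @param method `"mean"` (default) or `"median"`.
#' @param min_population population size below which `small_population` is
#'   flagged (default 49, the smallest population used in the source data).
#' @return Object of class `normalized_intensities`: `raw`, `relative`,
#'   `population_size`, `reference`, `small_population`.
#' @export
normalize_to_population <- function(values, population, method = c("mean", "median"),
                                    min_population = 49L) {
  method <- match.arg(method)
  if (!length(population)) stop("population must be non-empty")
  ref <- if (method == "mean") mean(population) else stats::median(population)
  if (!is.finite(ref) || ref <= 0) stop("population reference must be positive")
  structure(
    list(
      raw = values, relative = values / ref,
      population_size = length(population), reference = ref,
      small_population = length(population) < min_population
    ),
    class = "normalized_intensities"
  )
}

#' Munc13-1 / PSD-95 ratio and its coefficient of variation
#'
#' Element-wise ratio of the two channels per synapse, and the CV (n-1 sample
#' SD over mean) of the ratios. Size-independent variability in the priming
#' protein shows up as a nonzero ratio CV.
#'
#' @param munc13,psd95 equal-length intensity vectors; `psd95` entries > 0.
#' @return list with `ratios` and `cv`.
#' @export
ratio_cv <- function(munc13, psd95) {
  if (length(munc13) != length(psd95)) stop("channel vectors differ in length")
  bad <- which(psd95 <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive PSD-95 intensity at synapse %d", bad[1L]))
  }
  r <- munc13 / psd95
  list(ratios = r, cv = sd(r) / mean(r))
}

#' Spearman rank correlation with t-distribution p-value
#'
#' Pearson correlation of average-ranked values (ties receive average ranks);
#' the two-tailed p-value comes from t = rs * sqrt((n-2)/(1-rs^2)) against
#' Student's t with n-2 degrees of freedom. Perfectly monotone data
#' (|rs| = 1) report a p-value at the machine floor.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rs`, `p`, `n`, `degenerate` (TRUE when either vector is
#'   constant, in which case rs is NA).
#' @export
spearman_rs <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  n <- length(x)
  if (n < 4L) stop("need >= 4 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rs = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rs = rs, p = p, n = n, degenerate = FALSE)
}

#' Holm-Bonferroni step-down adjustment of p-values
#'
#' Step-down Holm adjustment with enforced monotonicity, capped at 1 (as
#' applied to correlation p-values computed repeatedly from the same data).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  p.adjust(pvals, method = "holm")
}
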