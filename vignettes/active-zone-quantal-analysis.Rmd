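---
title: "Quantal parameters and active-zone spatial statistics with azquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal parameters and active-zone spatial statistics with azquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azquant)
```

# Scope

`azquant` implements the computational side of a study of release-site
heterogeneity at hippocampal pyramidal-cell to fast-spiking-interneuron
synapses: multiple-probability fluctuation analysis (MPFA) of paired
recordings, spatial statistics of immunogold point patterns inside
active-zone (AZ) polygons, a binomial model of antibody-labeling
variability, and normalized-intensity comparisons. Raw recordings and
electron micrographs are not required: seeded generators produce all
inputs, and every analysis consumes either in-memory objects or plain CSV
files.

# The quantal model and MPFA

A connection is modeled as `N` independent release sites, each releasing at
most one vesicle per action potential with vesicular release probability
`Pv` and postsynaptic quantal amplitude `q` (pA). With `k ~ Binomial(N, Pv)`
released vesicles, the peak amplitude has mean `N q Pv` and variance
`N q^2 Pv (1 - Pv)`, so across pulse positions of a 40 Hz train - each a
different-`Pv` condition - the mean-variance relation is the through-origin
parabola `var = q mu - mu^2 / N`.

`mpfa_fit()` fits `var = a mu + b mu^2` by linear least squares and reports
`q = a`, `N = -1/b`, `Pv_i = mu_i / (N q)` and the first-pulse `pv1`.
Choices worth knowing:

* **Unweighted fit by default.** The source analysis names no weighting; an
  inverse-variance mode (weights `(n-1) / (2 var^2)`, the reciprocal of
  `Var[s^2]` under normality) is available for sensitivity analysis.
* **No quantal-variance correction term.** Intra-/inter-site quantal
  variability (`cv_q`) is a generator-side property only; the fitted
  parabola is the plain binomial one. With `cv_q > 0` the variance gains a
  `(1 + cv_q^2)`-type inflation that biases `q` slightly upward - a
  documented limitation, matching the printed form of the analysis.
* **Degeneracy guard.** Exactly linear points give a curvature that is zero
  only up to floating-point error; the fit is declared failed when
  `b >= -1e-10 * a / max(mu)` (an implied `N` beyond any physical range).
  This keeps genuine parabolas (where `b = -1/N` is orders of magnitude
  larger) untouched while returning a typed failure - not an exception - in
  the `Pv -> 0` limit, so batch pipelines continue.
* **QC rule.** `qc_exclude()` flags recordings whose largest mean also has
  the largest variance: all points then lie on the rising limb, maximal
  `Pv` likely never exceeded 0.5, and `N` is unidentifiable in practice.
  Ties on the mean are resolved toward exclusion (conservative).
* **`N` is reported as a positive real**; rounding is presentation-only.
* `mean_variance()` warns below 24 sweeps (the protocol's minimum);
  dropping instead of warning is a pipeline option (`sweep_rule = "drop"`).

Population-level helpers follow the same model: `variance_contributions()`
decomposes amplitude variability into CV-squared shares of `N`, `q`, `Pv`
(amplitude = `N q Pv`, so squared CVs add to first order; the printed
percentages do not name their decomposition, and CV^2 shares are the
natural first-order choice); `rescale_pv()` carries a high-calcium `Pv`
to 2 mM via the amplitude ratio, assuming calcium affects only `Pv`;
`allocate_n()` splits a fitted `N` across multi-contact connections
proportionally to PSD-95 intensity by the largest-remainder method with a
floor of one site per verified contact (the source does not state its
rounding; largest remainder is the standard integer apportionment, and
remainder ties break toward the larger synapse, then the lower index);
`release_probabilities()` evaluates `P_R = 1 - (1 - Pv)^N` and the
two-or-more-vesicle (multivesicular release) probability.

# Spatial statistics inside AZ polygons

Coordinates are in nm; areas are reported in um^2 (1 um^2 = 1e6 nm^2,
centralized). An `az_polygon` is a simple polygon stored counterclockwise;
points on the boundary count as inside (closed convention), matching
particles digitized on the AZ perimeter.

* **NND null.** `csr_null_nnd()` re-places the same number of points
  uniformly in the same polygon (default 200 replicates) and averages the
  per-replicate mean NNDs. The population test pairs each AZ's observed
  mean with its own null mean in `wilcoxon_signed_rank()` (exact for <= 25
  tie-free differences, normal approximation with continuity and tie
  correction otherwise). Pairing per AZ - rather than pooling distances -
  is chosen because the null is matched per AZ.
* **Ripley H.** `ripley_h()` estimates `K(r)` with the translation
  (Goreaud-Pelissier) edge correction, valid for polygonal windows without
  isotropy assumptions, then `H(r) = sqrt(K/pi) - r`. The pair weight needs
  the set covariance `|W intersect (W + v)|`, computed exactly by convex
  polygon clipping; a non-convex window falls back to its convex hull (with
  a warning). AZ outlines are near-convex, so the approximation is mild,
  but strongly concave windows would bias the correction. The default radii
  grid is 40 evenly spaced radii up to half the square root of the AZ area,
  and radii are capped at half the polygon diameter, where the estimator
  stops being informative.
* **MAD test.** `mad_test()` uses `T = max_r |H(r) - mean_null H(r)|`
  against the same statistic from CSR simulations (default 200), with the
  rank p-value `(1 + #{T_null >= T_data}) / (n_sim + 1)`, which can never
  be exactly zero. `clustered` additionally requires the data `H` to exceed
  the null mean at the maximizing radius, so regular (dispersed) patterns
  are not misclassified as clustered. Patterns with fewer than 5 points are
  refused ("insufficient"); the NND analysis only needs 2.
* **DBSCAN.** `dbscan()` counts the focal point in its own neighborhood
  (`MinPts = 2` means "at least one neighbor within eps") - conventions
  differ between implementations, so this is stated explicitly. Points are
  scanned in input order; border points tied between clusters join the
  first-discovered core cluster, making labels deterministic. For
  `MinPts = 2` the clusters coincide with the connected components (of size
  >= 2) of the eps-distance graph, which the tests exploit as a brute-force
  oracle.
* **Cluster workflow.** Mirroring the source flow, `run_pipeline()` runs
  DBSCAN only in AZs that pass the MAD test.

## The eps sweep

`eps_sweep()` scans integer eps from 1 to 100 nm and compares the mean
DBSCAN cluster count over the data AZs with the mean over CSR replicates
matched in point count and polygon (20 replicates per AZ by default - the
profile is an average over AZs x replicates, and 20 stabilizes it without
dominating the runtime; the original count is not stated). `eps_star` is
the eps with the largest absolute difference, ties toward the smaller eps;
a flat-profile flag fires when the maximal differential is below half a
cluster, which is the CSR-population signature.

The "difference between data and random" metric is not named in the source;
mean cluster count is the interpretation used here. Its behavior deserves a
candid note: for Gaussian clusters the data cluster count saturates once
eps reaches the *intra-cluster* nearest-neighbor spacing, while the CSR
count is still near zero, so the differential peaks at that spacing (about
8-11 nm for sigma = 12 nm with ~5 points per cluster) rather than at the
2-3 sigma scale. A secondary, smaller lobe of opposite sign (CSR forming
*more* clusters than the data) appears near 30-45 nm. Real immunogold data,
with its different within-cluster structure, can place the optimum at the
larger scale; with this package's Gaussian generator the recovered
`eps_star` tracks the intra-cluster spacing, and it does so monotonically
in sigma (tested over sigma = 5, 10, 20 nm).

# The binomial labeling model

`labeling_model(p, n_ep)` treats each epitope as labeled independently with
probability `p`, so counts are `Binomial(n_ep, p)` with
`cv = sqrt((1 - p) / (n_ep p))`. For the PSD-95 scenario (`p = 0.5`,
`n_ep = 80`) this gives mean 40 and CV 11%; dropping `p` tenfold with
tenfold more epitopes raises the CV only to ~15% because at fixed mean
`n_ep p` the CV saturates at `sqrt(1/(n_ep p))` as `p -> 0`.
`labeling_variance_fraction()` converts CVs to a variance share,
`(cv_label / cv_obs)^2`: with the observed 33% density CV, stochastic
labeling explains at most a quarter of the variance. Both the analytic and
the simulated (`simulate_labeling()`, n-1 SD) paths are exposed because the
printed values mix the two.

# Intensity analysis

`normalize_to_population()` divides by the arithmetic mean of a
surrounding-synapse population (the source used 49-89 synapses; smaller
populations are flagged, and a median option exists for robustness).
`ratio_cv()` is the per-synapse channel ratio with its n-1 CV - exactly
zero when the numerator is proportional to the denominator, and invariant
under common rescaling of either channel. `spearman_rs()` ranks with
average ties and takes the two-tailed p from the t-distribution with n-2
degrees of freedom, reporting the machine floor for perfectly monotone
data; `holm_bonferroni()` applies the step-down adjustment.

# The synthetic world

The generators' defaults are the measured conditions of the modeled
synapse population, fixed once:

| parameter | default | origin |
|---|---|---|
| AZ area | 0.071 um^2 | measured mean AZ area |
| area CV | 0.43 | measured AZ-size CV |
| gold per AZ | 26 | measured mean Munc13-1 count |
| clusters per AZ | 5 | measured ~5 clusters / AZ |
| Munc13-1 density | 383 / um^2, CV 0.33 | measured density and CV |
| PSD-95 density | 497 / um^2, exact scaling | measured density, CV ~0.09 treated as 0 |
| train | 6 pulses, 30 sweeps, noise 2 pA | recording protocol scale |
| quantal truth | N = 10, q = 30 pA, Pv 0.8-0.2 | population-scale values |

What the generators emulate: binomial quantal release with optional
depletion (off by default - MPFA treats pulses as independent-`Pv`
conditions, and the default generator matches that assumption); CSR or
Gaussian-clustered particle patterns (out-of-polygon draws are resampled,
not clipped, preserving within-cluster isotropy); binomial thinning of
epitopes; lognormal synapse sizes (parameterized by arithmetic mean and CV)
with exactly area-proportional PSD-95 and lognormally jittered Munc13-1
density.

What they do not emulate: current kinetics and rise times (only peak
amplitudes), facilitation, localization error of gold particles, 3-D
geometry, non-convex AZ shapes beyond mild star-polygon irregularity, and
correlations between synapse size and density noise. A green test therefore
establishes correctness of the estimators under the stated model, not
fidelity of the model to any particular dataset.

# Numerical choices and reproducibility

* All stochastic functions take an explicit integer seed and restore the
  caller's RNG state; identical seeds are bit-identical.
* Rejection sampling aborts after 1e6 rejections (degenerate polygons).
* Polygon areas use the shoelace formula; target areas are met to 1e-9
  relative tolerance by linear rescaling.
* Monte-Carlo p-values use the `(1 + b) / (1 + m)` estimator.
* CSVs are written with 17 significant digits so write/read round-trips
  are exact; `run_pipeline()`'s manifest omits timestamps so identical
  config + seed reruns are byte-identical, and derives each stage's seed
  deterministically from the run seed and a stage tag.
* CVs and SDs use the n-1 denominator throughout.

# Known limitations

* The MPFA parabola omits quantal-variance correction terms (see above).
* Translation edge correction uses the convex hull of non-convex windows.
* The eps-sweep differential is tied to the mean-cluster-count metric; see
  the candid discussion above for where its optimum lands on Gaussian
  clusters.
* `P_occ`-style occupancy quantities and image segmentation are out of
  scope; inputs are coordinates, amplitudes and integrated intensities.
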