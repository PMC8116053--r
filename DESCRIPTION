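Package: azquant
Title: Quantal Parameters and Active-Zone Spatial Statistics for Central Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for release-site heterogeneity at cortical
    synapses. Estimates quantal parameters (number of release sites N, quantal
    size q, vesicular release probability Pv) from paired-recording EPSC sweep
    tables by multiple-probability fluctuation analysis (MPFA), quantifies the
    sub-active-zone distribution of immunogold-labeled presynaptic proteins
    with nearest-neighbor, Ripley H and DBSCAN statistics inside active-zone
    polygons, models antibody-labeling variability as a binomial thinning
    process, and compares normalized per-synapse fluorescence intensities.
    Ships seeded synthetic-data generators that emulate each input so the whole
    pipeline is testable without raw recordings or micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
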