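Package: conntop
Title: Longitudinal Functional Brain Network Topology and Network-Based
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Graph-theoretical analysis of longitudinal (pre/post) resting-state
    functional connectomes. Builds Pearson correlation networks from ROI time
    series, extracts intrinsic subnetworks (default mode, fronto-parietal,
    cingulo-opercular) from an atlas, thresholds them over a sparsity grid whose
    lower bound is set by a minimum-edge rule, and computes weighted topological
    metrics (global/local efficiency, characteristic path length, clustering,
    and small-world indices normalized by degree-preserving null networks)
    summarized as areas under the curve across the grid. Inference is
    non-parametric: paired sign-flip permutation tests on AUC values,
    Benjamini-Hochberg correction for nodal metrics, the network-based statistic
    (NBS) with permutation family-wise error control over connected components
    of suprathreshold edges, Wilcoxon signed-rank tests for clinical scales, and
    partial correlation of topological change with clinical change. A synthetic
    cohort generator with block covariance structure, AR(1) temporal
    autocorrelation and planted pre-to-post connectivity effects provides ground
    truth for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
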