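---
title: "Longitudinal connectome topology: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal connectome topology: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conntop)
```

## The analysis in one paragraph

`conntop` implements a pre/post (baseline vs endpoint) graph-theory analysis
of resting-state functional connectomes. Nodes are atlas ROIs; edges are
Pearson correlations between ROI time series. Three intrinsic subnetworks —
default mode (DMN, 34 nodes), fronto-parietal (FPN, 21 nodes) and
cingulo-opercular (CON, 32 nodes) in the reference layout — are extracted
from the whole-brain matrix and analyzed as smaller but structurally
identical weighted graphs. Because any single correlation threshold is
arbitrary, each subnetwork is thresholded over a *sparsity grid* and every
topological metric is summarized by its area under the curve (AUC) across
the grid. Group inference is non-parametric throughout: sign-flip
permutation tests on AUC values, FDR for nodal metrics, the network-based
statistic (NBS) for edge-level effects with family-wise error control over
connected components, and partial correlation (age and sex as covariates,
Bonferroni over the family) for brain–behavior coupling.

## Sparsity grid

Sparsity is the fraction of retained edges out of `N(N-1)/2`. Retained edge
count at sparsity `s` is defined as `K = floor(s * N(N-1)/2)`; the floor
convention is forced by the requirement that the grid's printed lower bounds
be reproducible from the rule below (round-half-up would shift the 21-node
bound). The lower bound of the grid depends on network scale: it is the
smallest lattice value whose edge count is *strictly greater* than
`(N/2) ln N`, which keeps sparse graphs estimable; the upper bound is the
conventional 0.4, and the step is 0.01.

```{r}
sapply(c(DMN = 34, FPN = 21, CON = 32), sparsity_lower_bound)
length(sparsity_grid(32))   # 29 grid points for the CON
```

Products like `0.30 * 210` are not exact in binary floating point, so the
edge count is computed as `floor(s * E_max + 1e-9)`; the nudge is far below
one edge and only protects exact lattice products.

Edges are ranked by signed correlation (strongest positive first) with a
deterministic `(weight desc, i asc, j asc)` tie-break, so the retained sets
are nested across the grid and reproducible bit for bit. How negative
correlations should be treated at threshold time is genuinely open in this
literature; the package retains them by rank but clamps their weight to zero
with a warning, because the weighted metrics below assume nonnegative
weights. At the sparsity levels of the default grids on positively coupled
subnetworks, negative edges essentially never reach the retained set.

## Topological metrics

All metrics operate on the weighted thresholded graph, with shortest-path
edge length `1/w` (the standard mapping for correlation weights: stronger
coupling, shorter functional distance).

* **Global (network) efficiency** `E_net = mean over pairs of 1/d_ij`
  (with `1/Inf := 0`) — functional integration.
* **Characteristic path length** uses the *harmonic* form
  `L_p = 1 / E_net`. This is robust to disconnection, which matters at the
  sparse end of the grid; the identity `L_p * E_net = 1` is regression
  tested. An arithmetic mean over connected pairs is available via
  `method = "mean"`.
* **Clustering** is the Onnela form: weights normalized by the network
  maximum, per-node geometric mean of triangle weights over neighbor pairs.
  This convention was fixed once (it is the most common weighted
  generalization) and is enforced by brute-force oracles in the test suite.
* **Local efficiency** is the mean over nodes of the global efficiency of
  each node's neighbor-induced subgraph, weights retained.
* **Nodal metrics**: degree is the weighted strength (sum of retained
  weights; a binary switch exists since the binary reading is also
  defensible), nodal efficiency is the per-node mean inverse distance, and
  betweenness is unnormalized weighted betweenness with even splitting
  across tied shortest paths.
* **Normalized metrics**: `gamma = C_p / C_p_rand`,
  `lambda = L_p / L_p_rand`, `sigma = gamma / lambda`, with the null means
  taken over degree-preserving Maslov–Sneppen rewired surrogates (10 swap
  attempts per edge) whose edge-weight multiset is shuffled onto the rewired
  topology. The default of 100 surrogates per grid point balances the
  Monte-Carlo error of the null means against runtime; complete graphs admit
  no rewiring and degenerate (with a warning) to a weight shuffle, which
  correctly gives `gamma = lambda = sigma = 1` there.

AUC over the grid uses the trapezoidal rule by default (a rectangle rule is
available); a constant curve `c` integrates to `c * (upper - lower)`
exactly. A subject-session whose curve contains non-finite values — rare
under the harmonic path-length convention — is excluded from AUC with a
warning rather than silently imputed.

## Permutation inference

For paired designs the exchangeable quantity is the within-subject session
label, so the permutation engine flips the sign of each subject's paired
difference. The test statistic is the mean paired difference of AUC values
(the simplest location statistic; the choice matters little at `n = 10`
because the flip set is identical for any monotone statistic). Two
conventions coexist deliberately:

* **Exhaustive enumeration** whenever `2^n <= n_perm`: the p-value is the
  exact proportion `#{|null| >= |observed|} / 2^n` over all sign
  assignments. Ten identical positive differences give `p = 2/1024`.
* **Monte-Carlo** otherwise, with the add-one estimate
  `(1 + #hits) / (1 + n_perm)` so p is never 0.

The default `n_perm = 10000` matches the NBS permutation count. Network
metrics are tested at uncorrected 0.05 and nodal metrics under
Benjamini–Hochberg FDR at 0.05, both overridable. Clinical scales use the
paired Wilcoxon signed-rank test (exact for up to 25 untied non-zero
differences, tie-corrected normal approximation without continuity
correction otherwise — the no-continuity choice keeps perfectly symmetric
difference sets at exactly `p = 1`). Brain–behavior coupling is the Pearson
correlation of residuals after regressing both change scores on intercept,
age and a sex indicator, with `df = n - 2 - k`; the Bonferroni family size
is an explicit user input because the correlation family (which metrics ×
which scales) is a study-level decision.

## Network-based statistic

NBS runs on the *unthresholded* subnetwork correlation matrices
(thresholding is the metric pipeline's concern): paired two-tailed t-tests
at every edge, suprathreshold mask at `p < 0.001`, connected components by
breadth-first search, component size = edge count. The null distribution of
the maximal component size is built by randomly exchanging pre/post labels
per subject (equivalent to sign flips of the paired differences), refitting
the edgewise tests under the same threshold, and recording the maximal
component; a component is family-wise significant when its size ranks in
the top 5% of the permuted maxima. Positive and negative suprathreshold
edges are pooled into common components by default — the two-tailed primary
test does not separate directions — and every component is annotated with
the sign of its t-values so "increased connectivity" components are
identifiable; per-direction runs are possible by filtering on that
annotation. Zero-variance edges with a nonzero mean difference are treated
as suprathreshold (they are infinitely significant under the t model) with
a warning. The permutation loop is vectorized across edges and chunked so
memory stays flat for whole-brain inputs.

## Synthetic cohorts

No subject-level data are deposited for this family of pilot studies, so the
package ships a generator that produces cohorts with *known* ground truth:

* **Spatial structure**: a blockwise correlation matrix — `r_within = 0.2`
  inside each subnetwork, `r_between = 0.05` across — emulating the
  community structure of intrinsic networks at typical resting-state
  coupling strengths.
* **Planted effect**: the post-session covariance raises a connected edge
  set inside one subnetwork (default: 6 edges on 5 CON nodes) by
  `delta = 0.25`. The studied design (10 subjects, 190 retained volumes,
  160 ROIs) motivates the default cohort shape; `delta` is a calibration
  choice — pilot papers in this area do not report connectivity effect
  sizes — picked once so that edge-level effects are comfortably detectable
  at `n = 10` while global-metric effects remain subtle, which mirrors how
  such studies actually behave.
* **Temporal structure**: Gaussian innovations spatially colored by the
  Cholesky factor, then AR(1)-filtered (`phi = 0.3`) with the variance
  renormalized so the target covariance is the *stationary* spatial
  covariance; `x_1` is drawn at full stationary variance so no burn-in is
  needed. This reproduces the band-limited autocorrelated character of
  preprocessed BOLD well enough for inference testing; it deliberately
  omits hemodynamic response shapes, motion artifacts and scanner noise
  spectra, so passing calibration here certifies the *statistics*, not
  robustness to acquisition artifacts.
* **Subject heterogeneity**: a symmetric perturbation (sd 0.05) of the edge
  correlations, shared between a subject's two sessions so that paired
  differences isolate the planted effect plus sampling noise. Any
  covariance that loses positive definiteness is repaired by flooring
  eigenvalues at 1e-6 and rescaling to unit diagonal.
* **Clinical coupling**: the ERC (emotion regulation) change equals
  `beta * (realized mean planted-edge correlation change) + noise`, with
  `beta = 20` ERC points per unit correlation change (sized so the default
  planted effect maps to a ~5-point mean ERC improvement, the magnitude
  typical of such trials) and noise sd `0.1 * beta`. Coupling to the
  *realized* (sample) change rather than the population delta gives the
  generated scores genuine subject-level association with the measured
  topology. The other scales (CDRS-R, YMRS, CGAS) are drawn around
  realistic baseline means and mean changes and carry no planted coupling.
* **Reproducibility**: one master seed; per-subject substreams are derived
  from it and a stable hash of the subject id, so any subject subset
  regenerates identically.

`bandpass_detrend()` is a small frequency-domain utility (linear detrend +
FFT band mask) for experimenting with synthetic series; the analysis
pipeline itself consumes preprocessed ROI series as given and performs no
image-space preprocessing.

## Problem sizes used by the test suite

The shipped suites exercise the pipeline at sizes chosen to make the
statistical checks sharp while keeping a full run comfortable on a laptop
core: oracle equivalence on 200 random graphs of up to 8 nodes;
permutation-test calibration on 500 null cohorts of 10 subjects
(exhaustive, 1024 flips each); NBS family-wise false-positive rate on 200
null cohorts and recovery of the planted component on 50 cohorts
(32-node single-subnetwork atlas, 190 time points, 1000 permutations —
the NBS operates on the extracted subnetwork, so a single-subnetwork atlas
exercises the identical code path); covariance fidelity at 20,000 time
points. Production analyses would typically use `n_perm = 10000` and
`n_null = 100` as the defaults encode.

## Known limitations

* Edge weights are raw Pearson r (no Fisher z option), matching the
  analysis the package implements; absolute-value weighting and
  unpaired/between-group designs are out of scope.
* The harmonic `L_p` makes `L_p` and `E_net` deterministic functions of one
  another, so testing both at the same level is redundant by construction —
  they are both reported because the field reports both.
* Whether nodal "degree" should be weighted strength or binary degree is
  unstated in much of the applied literature; strength is the default here
  and the binary switch is explicit.
* The AUC integration rule (trapezoid vs rectangle times step) differs by a
  near-constant factor on smooth curves and does not change paired
  inference; trapezoid is the default.
* The generator's Gaussianity means heavy-tailed motion-contaminated data
  may behave worse than the calibration suites suggest; permutation
  inference remains valid under exchangeability but power claims transfer
  only qualitatively.
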