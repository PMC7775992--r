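---
title: "Methods: time-resolved coupling, metastates and network inference in dynfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved coupling, metastates and network inference in dynfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and limitations of
`dynfc`. It states no empirical result that the test suite does not itself
compute.

## The analysis model

The pipeline treats a task fMRI session as a sequence of short coupling
states. Per run, ROI time series (volumes × nodes, TR = 2 s) are first
residualised against HRF-convolved task regressors, because shared evoked
responses inflate any coupling estimate. Coupling itself is the
multiplication of temporal derivatives (MTD): first differences of each
node's series, normalised by the sample SD of that node's derivative
vector, multiplied pairwise at each time point. Because the derivative
operation removes slow shared activation and the normalisation removes
amplitude, MTD is robust against task-locked inflation and invariant to
per-node affine rescaling of the input (tested to 1e-10).

Pointwise MTD is extremely noisy; it is averaged over non-overlapping
windows of 15 derivative points (30 s). Windows are defined on derivative
time points rather than volumes — for 179 volumes both conventions give
`floor(178/15) = 11` windows per run, so the printed counts (11 per run,
33 over three runs) are insensitive to this choice, but the derivative
grid is the internally consistent one.

## Multilayer community structure

Each window is a graph layer. Negative window weights are set to zero for
community detection and the cartographic metrics (strength-based measures
assume non-negative weights); the signed values are retained for network
averaging. The quality function is the multislice modularity with
resolution γ = 1 and inter-layer coupling ω = 1. Two choices deserve
comment:

* **Ordinal coupling.** The inter-layer term couples each node only to
  itself in adjacent layers (`|s − r| = 1`), the standard choice for
  time-ordered layers; all-to-all coupling would treat windows as
  exchangeable categories, which they are not.
* **One multilayer network per participant.** Community structure is found
  once per repetition over the pooled, time-ordered sequence of all
  windows from all runs (33 layers), not per run. Per-run detection gives
  community labels in incompatible frames: a run spent mostly in an
  integrated state can merge two systems for that run only, which shifts
  the participation-coefficient scale of that run's windows and corrupts
  any clustering pooled across runs. Pooled detection keeps one label
  frame; run boundaries are still respected where they matter (flexibility
  and metastate switch counts never count transitions across runs).

The optimiser is a dense Louvain with seeded stochastic sweep order plus
aggregation. Greedy single-node moves cannot coordinate the splitting of a
community that has spuriously merged across a stretch of layers, so the
optimiser is run from two starts — the usual all-singleton start, and a
start seeded from the static (mean-network) partition replicated across
layers — and returns whichever final partition scores higher. The result
is additionally guarded against the two trivial partitions (all-singleton,
one community), so the reported Q is never below either baseline. On
instances small enough for exhaustive enumeration over all set partitions
(≤ 12 node-slices), the optimiser reaches the global optimum in ≥ 95% of
seeded runs (tested).

## Cartographic profiles and metastates

Per window, each node's participation coefficient (PC, between-community
connectivity) and module degree z-score (MDZ, within-community
connectivity) are computed against that window's community labels, and
binned into a 10 × 10 joint histogram. Bin edges are fixed — PC on [0, 1],
MDZ clipped to [−3, 3] — so profiles are comparable across windows and
participants; the MDZ support is a convention (the histogram's source
studies do not state one) and clipping affects only extreme outliers. The
per-axis resolution (10) is configurable, mirroring the published
exploration of CP resolution.

k-means with k = 2 (Euclidean, 10 restarts, seeded) clusters one
participant's profiles, pooled across runs, within each repetition of the
non-deterministic community stage. The cluster whose centroid puts more
mass at high PC (mass-weighted mean of PC bin centres) is named
*integrated* — PC is the between-community connectivity measure, so high
PC is what "integrated" means here; this rule makes the state semantics
invariant to k-means' arbitrary cluster indices. Identical profiles across
all windows are refused (no clustering is possible). Because the community
stage is stochastic, the whole labelling is repeated (100 repetitions in
the reference configuration; tests use 2–5, which leaves labelling
accuracy unchanged) and each repetition's integrated windows are averaged;
the final integrated network is the unweighted mean across repetitions
(weighting by integrated-window count was considered and rejected as it
would let noisy low-integration repetitions shrink silently).

## Network Based Statistics

Per upper-triangle edge, the integrated (or static) network value is
regressed on `[intercept | contrast | covariates]`; the statistic is the
1-df partial F for the contrast (equal to the squared equal-variance
two-sample t for a binary group contrast without covariates, tested).
Edges at or above an F threshold form a graph whose connected components
are the candidate sub-networks; component size is edge count (extent).
Significance comes from permutations of the maximal null extent with the
Freedman–Lane scheme — residuals of the covariate-only model are permuted
and added back to the reduced fit before refitting — the standard
covariate-safe choice; whether the source analyses permuted raw responses
is unknown. p-values use the +1 correction, so they are never exactly
zero and are monotone non-increasing in extent. The threshold sweep (6–28
by default) shares one permutation stream across thresholds. Cohen's
f² = (R²_full − R²_reduced)/(1 − R²_full) is reported per edge, over all
edges and over any edge subset; R²_full = 1 is flagged infinite rather
than propagated.

The family-wise error calibration criterion drives 200 null cohorts
through this machinery using each participant's static all-window mean
MTD network rather than the full metastate network — the permutation
inference path under test is identical, and the metastate stage would add
only runtime under a null where the response is independent of all
networks.

## The synthetic cohort: what it emulates, and what a green test establishes

The generator produces multi-run ROI series from a two-state hidden
Markov regime operating at the window grain (15 TR), so ground truth
aligns with the analysis windows and labelling accuracy is a well-defined
score. Within a window, volumes are drawn i.i.d. from a zero-mean
multivariate normal: in the *segregated* regime, correlation
`coupling_within` inside each of the a-priori systems and none between;
in the *integrated* regime, cross-system correlation `coupling_between`
is added. HRF-convolved event responses (canonical double-gamma: gamma
densities with shape 6 and 16, rate 1, ratio 1/6 — peak near 5 s,
undershoot near 15 s; the convention, since no HRF is specified upstream)
are added to three designated task nodes. FD and DVARS traces are
log-normal with configurable parameters; phenotypes carry group, age,
sex, binary past-or-present medication flags, follow-up interval, and
baseline/follow-up symptom scores.

Key calibration choices, fixed during generator design and then frozen:

* `coupling_within = 0.8`, `coupling_between = 0.65`, `noise_sd = 0.2`.
  A 15-point MTD window estimate has sampling noise of roughly 0.26 per
  edge with strong common-mode structure across edges, so weak couplings
  produce regimes that are not statistically identifiable from single
  windows by *any* method — the generator would then fail to contain the
  "known alternating regimes" it promises. The chosen values are at the
  strong end of plausible ROI-level task fMRI coupling; they make the
  regimes separable while keeping `between < within` so community
  structure never collapses during integration.
* Dwell probabilities 0.8 (integrated) and 0.7 (segregated) give a
  stationary 60% integrated occupancy, matching the ballpark reported for
  task cohorts.
* The planted sub-network is the complete graph over five nodes spread
  across systems (10 edges). Cross-system placement leaves coupling
  headroom below `coupling_within` for the per-participant planted
  increment (uniform on [0, 0.2]), which is what makes planted-edge
  coupling vary across participants; positive-definiteness is verified by
  Cholesky and the increment halved if needed. The symptom-change score
  is constructed as `planted_beta ×` (the participant's mean planted-edge
  MTD over truly integrated windows) plus small fixed covariate terms
  plus noise, so the model is exactly recoverable from the truth record.

What a green test does establish: the pipeline recovers planted regime
labels (≥ 95%), responds monotonically to cross-system coupling, controls
family-wise error under the null, and recovers a planted sub-network with
the planted sign. What it does not establish: performance on real BOLD
data with autocorrelated noise, scanner drift, physiological artefacts,
spatially varying haemodynamics, or coupling magnitudes weaker than the
stylised world — in particular, single-window metastate labelling on real
data is expected to be substantially noisier.

## Degenerate inputs and tie-breaking

Zero-variance derivative vectors are an error naming the node; all-zero
window layers are kept with a warning and contribute only coupling terms;
isolated nodes get PC 0; modules with fewer than two members or zero
spread get MDZ 0; repetitions with no integrated window are skipped with a
warning, and a participant with none at all is an error. k-means ties and
Louvain sweep order are controlled by seeds derived from one root via a
counter scheme (`derive_seed`), so any sub-result is reproducible in
isolation; reruns with the same seed are bitwise identical (tested).

## Known limitations

* High-pass filtering and image-level preprocessing are upstream
  boundaries: inputs are assumed residualised of drift.
* The exhaustive optimality oracle is limited to ~12 node-slices by the
  Bell-number growth of set partitions; optimality on large instances is
  supported only indirectly (baseline guards, dual-start).
* Only k = 2 metastates receive semantic labels; larger k is a
  configuration pass-through without integrated/segregated semantics.
* The cohort report's group tests are descriptive and uncorrected.
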