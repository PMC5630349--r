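---
title: "Small-world analysis of resting-state connectomes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world analysis of resting-state connectomes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsconnectome)
```

## The analysis in one paragraph

`rsconnectome` turns per-subject regional resting-state time series into
binary brain graphs and asks two questions: does each subject's network
show small-world organisation, and do two groups differ in global or
nodal topology in a way that tracks behaviour? The pipeline is:
time-series cleaning (detrend, 0.01–0.10 Hz ideal bandpass, nuisance
regression, motion scrubbing by framewise displacement), Pearson
correlation between all region pairs with the Fisher r-to-z transform,
binarization by ranking |z| at each value of a sparsity grid,
graph metrics per graph (clustering `C_p`, path length `L_p`, global,
local and nodal efficiency, degree, betweenness), normalisation of
`C_p` and `L_p` against degree-preserving rewired null networks to give
`gamma`, `lambda` and the small-worldness `sigma = gamma / lambda`,
trapezoidal area-under-curve (AUC) summaries across the grid, and
finally pooled t-tests on the global curves, covariate-adjusted
permutation tests on nodal AUCs, and partial-correlation screens
against behavioural scores.

## Preprocessing model and its assumptions

Framewise displacement at frame *t* is the sum of the absolute
frame-to-frame changes of the six rigid-body parameters, with each
rotation difference converted from degrees to millimetres as arc length
on a 50 mm sphere (roughly the mean distance from the centre of
template space to the cortex). The first frame has no predecessor, so
its displacement is defined as zero. Frames with FD above the
scrubbing threshold — 0.3 mm by default, settable via `fd_threshold` —
are deleted outright: no interpolation and no spike regressors, which
keeps the retained samples untouched at the cost of non-uniform
sampling afterwards.

The pipeline order is fixed: drop initial volumes, detrend, bandpass,
nuisance regression, then scrubbing, with FD always computed from the
raw motion trace. Filtering before deletion is deliberate: the ideal
(rectangular) frequency-domain filter assumes a uniform sampling grid,
so it must run while the grid is still uniform; deleting frames first
would make the spectrum ill-defined, while filtering first at worst
spreads a little spike energy that scrubbing then removes. The
bandpass is an ideal filter — Fourier bins inside [low, high] kept,
all others zeroed — rather than an IIR design, trading roll-off
realism for an exactly known passband, which is also what makes its
tests sharp (bin-aligned sinusoids pass or vanish almost exactly).

Nuisance regression residualises each region against an intercept plus
caller-supplied columns. Signal extraction from tissue masks
(white-matter, CSF or component signals) is upstream image-space work
and out of scope; those signals enter as plain numeric columns.

## Network construction

Edges are ranked by |z|: strong negative correlations become edges just
like positive ones. This matters because the pipeline performs no
global-signal regression, the step most likely to manufacture spurious
anticorrelations; with that step absent, large negative couplings are
treated as real connectivity. Binarizing at sparsity *s* keeps the top
`K = round(s * N(N-1)/2)` pairs, with rank ties broken by (row,
column) order so results are bit-reproducible. Rounding K to nearest
(rather than up or down) is a convention; at N = 90 the three choices
differ by at most one edge.

The sparsity grid defaults to 0.11–0.44 in steps of 0.01. The lower
bound is the smallest grid value at which the mean degree
`s * (N - 1)` exceeds `2 ln N` (at N = 90: `0.11 * 89 = 9.79 > 9.00`,
while 0.10 fails), below which sparse-graph metrics become unstable;
the upper bound is where the weakest subject's small-worldness would
drop to 1.1, computable from data via `maximum_sparsity()`.

## Graph metrics and numerical choices

All metrics operate on binary undirected adjacency matrices. Two
conventions deal with disconnection, which is routine at low sparsity:

* efficiencies use `1/Inf = 0` for unreachable pairs, so they are
  always defined;
* path-length means exclude infinite distances (and isolated nodes are
  excluded from `L_p` with a warning), rather than poisoning the mean.

Clustering of a degree-0 or degree-1 node is 0, not undefined, keeping
`C_p` well-defined everywhere. Betweenness is the unnormalized Brandes
sum over unordered pairs; a normalized variant is an option. Local
efficiency of node *i* is the global efficiency of the subgraph induced
on *i*'s neighbours with *i* itself removed — the fault-tolerance
reading — which is distinct from nodal efficiency (inverse harmonic
mean of *i*'s distances to everyone); the package implements both as
separate functions.

Null networks come from Markov-chain double-edge swaps that preserve
every node's degree, with a swap budget of 10 × edge count per null —
a standard mixing heuristic. `sigma = gamma / lambda` with
`gamma = C_p / mean(C_random)` and `lambda = L_p / mean(L_random)`
over 100 nulls by default (the Humphries–Gurney convention; the
criterion `gamma > 1`, `lambda ≈ 1` makes this the only ordering that
can exceed 1 on lattice-like graphs). Nulls with no defined path
length are regenerated with a fresh sub-seed, at most 10 retries.

AUC uses the trapezoid rule on the uniform grid and is linear in the
curve, so group differences in AUC are exactly the AUC of the group
difference curve.

## Inference

Global curves are compared by pooled-variance two-sample t-tests at
every grid point and on each metric's AUC, uncorrected — these are
descriptive scans, not confirmatory tests. Nodal AUCs get a
permutation test: covariates (age, mean FD) are regressed out of every
node's AUC across all subjects, then group labels are permuted
(residualize-then-permute; the statistic is the difference of group
means of residuals), with `p = (1 + #{|null| >= |observed|}) /
(1 + n_perm)` so p is never exactly zero. Tests are two-sided
throughout. Behavioural screens use partial correlation (Pearson on
residuals after covariate removal, `df = n - 2 - k`), flagged both at
the per-node threshold 1/N (0.011 for 90 nodes) and at nominal 0.05.
Zero residual variance is reported as undefined `r`, never silently
propagated.

## What the synthetic generator emulates — and what it does not

`simulate_study()` builds two groups of subjects from known ground
truth so that every downstream stage has a recoverable target. Each
subject gets a Watts–Strogatz graph (default 90 nodes, neighbourhood
k = 10, rewiring probability 0.1 — a regime that is reliably
small-world); group B additionally has a planted lesion: at each
affected node, a fraction of edges is rewired to random non-neighbours.
Time series are multivariate Gaussian draws with covariance
`I + w A` (eigenvalues clipped at 1e-6 when the dense case goes
indefinite); motion traces are slow random walks with optional
persistent step displacements that downstream scrubbing must find;
behavioural scores are linear in a chosen node's true nodal efficiency
plus Gaussian noise, with `behavior_noise_for_r()` solving for the
noise level that gives a target population correlation. All randomness
flows from one master seed through `derive_seed(master, stage,
subject)`, so any stage can be regenerated in isolation and full
datasets are bit-reproducible.

Default study conditions mirror the reference design: 2 × 18 subjects,
90 regions, 97 frames at TR = 3 s. The adjacent-pair covariance
defaults to `w = 0.4` (population correlation ≈ 0.36 after clipping) —
a realistic adjacent-region resting-state correlation, and strong
enough that top-K binarization at the generator's own sparsity
recovers most true edges at 97 frames; at `w = 0.5` and a few hundred
frames recovery exceeds 95%.

The generator deliberately omits: hemodynamic response and BOLD
physics, physiological noise spectra, spatial structure (there are no
voxels, only regions), non-Gaussian marginals, and any dependence
between motion and signal. Consequently, passing recovery tests shows
the *pipeline arithmetic* is sound — signals planted in graph space
survive the trip through time series, correlation, thresholding and
inference — not that the pipeline is robust to the artefact structure
of real scanner data.

### A note on the planted lesion's signature

Because the lesion rewires an affected node's edges while preserving
its degree, its true-graph signature is: degree unchanged, local
clustering and local efficiency sharply lower (the neighbourhood is
dispersed), nodal efficiency somewhat *higher* (the rewired edges act
as shortcuts). Recovery tests therefore treat detection as two-sided
and look across nodal metrics including per-node clustering; a lesion
model that lowered degree or efficiency would need edge deletion,
which would change the global edge count and confound group
comparisons of every density-dependent metric.

## Problem sizes used in validation

The test-suite simulations are scaled to keep the full suite fast
while leaving effect sizes honest: oracle equivalence uses 1,000
random graphs of up to 8 nodes against exhaustive brute force;
null-model checks use the full 90-node, 100-null configuration;
permutation calibration uses 500 null replicates of 2 × 18 subjects at
500 permutations; recovery uses 500 replicate cohorts of 2 × 18
subjects on 20-node, k = 6 graphs with 200 frames, a three-point
sparsity grid (0.15/0.25/0.35), full-strength lesions at three nodes,
and 200-permutation tests. These sizes were chosen once, from pilot
effect-size measurements at the generator's defaults, as the smallest
configurations in which the planted effects are comfortably
detectable; they are stated here so they can be scaled up rather than
rediscovered.

## Known limitations

* Binary graphs only; no weighted-graph variants.
* No multiplicity correction beyond the 1/N rule for behavioural
  screens — by design, matching the descriptive character of the
  per-sparsity scans.
* The ideal bandpass has sharp spectral edges (ringing in time); an
  IIR alternative is not provided.
* `maximum_sparsity()` needs sigma for every subject at every grid
  point, which is the single most expensive computation in the
  pipeline (subjects × grid × nulls); `connectome_study()` therefore
  takes a fixed grid by default.
* Partial correlation assumes linear confound action; no rank-based
  option.
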