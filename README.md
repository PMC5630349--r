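# rsconnectome

Graph-theoretical analysis of resting-state functional brain networks
in R: from regional time series to small-world statistics, group
inference, and brain–behaviour correlation.

## The problem

Resting-state fMRI studies of clinical populations often ask whether a
disorder reorganises the brain's functional network rather than any
single connection. The standard recipe parcellates the brain into *N*
regions (e.g. the 90-region AAL cerebrum), correlates every pair of
regional time series, thresholds the correlation matrix into a binary
graph at each value of a sparsity grid, and compares graph-theoretical
summaries between groups. `rsconnectome` implements that recipe as a
tested, seed-reproducible pipeline for two-group studies, plus a
synthetic-data generator with known ground truth so the whole chain
can be validated end to end.

## The model

For subject time series cleaned by detrending, 0.01–0.10 Hz ideal
bandpass filtering, nuisance regression and motion scrubbing
(framewise displacement FD_t = Σ|Δd_i|, rotations converted to mm at
r = 50 mm; frames with FD_t > 0.3 mm deleted), connectivity is
z_ij = atanh(r_ij) with r_ij the Pearson correlation of regions i and
j. At each sparsity S in 0.11–0.44 (step 0.01) the K = round(S·N(N−1)/2)
pairs of largest |z| become edges. Per graph:

- clustering C_i = E_i / (K_i(K_i−1)/2), C_p = mean(C_i)
- path length L_i = mean of finite hop distances, L_p = mean(L_i)
- efficiencies E_glo = mean over pairs of 1/d_ij (1/∞ = 0),
  E_nodal(i), E_loc = mean over i of E_glo of i's neighbour subgraph
- degree Deg_i and unnormalized betweenness BC_i
- small-worldness σ = γ/λ, with γ = C_p/⟨C_random⟩ and
  λ = L_p/⟨L_random⟩ over 100 degree-preserving rewired null networks

Each metric's curve over the grid is summarised by its trapezoidal
AUC. Groups are compared by pooled t-tests (global curves and AUCs)
and by covariate-adjusted permutation tests on nodal AUCs (age and
mean FD regressed out, labels permuted, 5000 iterations by default);
nodal AUCs are screened against behavioural scores by partial
correlation with a per-node significance threshold of 1/N.

## Worked example

Simulate a small two-group study with a known lesion — at nodes 4, 10
and 16, every edge of the node is rewired to a random non-neighbour in
group B — and analyse it:

```r
library(rsconnectome)
spec <- ground_truth_spec(n_nodes = 20, n_per_group = 12, n_timepoints = 150,
                          k = 6, affected_nodes = c(4, 10, 16),
                          degradation_fraction = 1, edge_weight = 0.5,
                          behavior_node = 4, seed = 42)
dat <- simulate_study(spec)
fit <- connectome_study(dat, grid = sparsity_grid(0.15, 0.35, 0.05),
                        n_random = 20, n_perm = 1000, seed = 42)
summary(fit)
```

```
Quality control
  mean FD: 0.029 mm (range 0.022-0.043); 23 frames scrubbed in total

Global metric AUC comparisons (pooled t)
  cp      t =  2.507  p = 0.0201
  lp      t =  1.678  p = 0.1076
  eglo    t = -2.708  p = 0.0128
  eloc    t =  2.777  p = 0.0110
  gamma   t =  2.556  p = 0.0180
  lambda  t =  1.964  p = 0.0623
  sigma   t =  2.331  p = 0.0293

Nodal permutation tests (covariate-adjusted)
  degree       4 node(s) with p < 0.05: 4, 7, 12, 19
  efficiency   4 node(s) with p < 0.05: 7, 12, 18, 19
  betweenness  3 node(s) with p < 0.05: 1, 7, 13
```

Reading the output: scrubbing found the motion spikes the generator
planted (23 frames across 24 subjects). The lesioned group shows lower
clustering and local efficiency but *higher* global efficiency AUC
(t < 0 means group B larger) — exactly the signature of a
degree-preserving lesion, whose rewired edges act as random shortcuts
— and the permutation tests flag planted node 4 among the nodal degree
differences. `plot(fit)` draws the group-mean metric curves and the
cost-efficiency curve (E_glo − S, maximal near S ≈ 0.2 for
small-world networks).

The same entry points run on real data: lay out per-subject
time-series and motion files plus a `subjects.tsv` manifest (see
`?write_study` for the exact shapes), then
`connectome_study(read_study("mystudy/"))`.

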