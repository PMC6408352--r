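---
title: "Rectangular tensor clustering and crosstalk model selection: methods"
author: "recticluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rectangular tensor clustering and crosstalk model selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A complete multi-indexed experiment — for example, phosphorylation
time courses of 36 breast-cancer cell lines exposed to 14 ligands at two
doses, three time points and two readouts (pERK, pAKT) — is a real tensor
`Z` of order `h`. Each *experiment* is one (cell line, ligand) pair, i.e.
one slice over the trailing axes. The package answers two questions:

1. Which experiments behave alike? — but with the constraint that each
   cluster must be a **rectangle**: a full Cartesian product of a cell-line
   subset and a ligand subset (not necessarily contiguous; no ordering of
   rows or columns is assumed). Rectangularity is what makes a cluster
   mechanistically interpretable: "these cell lines respond this way to
   these ligands", the pattern expected when the cells share a lesion that
   reroutes the response to a family of ligands.
2. What mechanism explains each cluster? — answered by enumerating a
   combinatorial family of three-species ordinary differential equation
   (ODE) models of receptor/pERK/pAKT crosstalk, fitting each to the
   cluster's mean response, and ranking them by the small-sample-corrected
   Akaike information criterion (AICc).

# Similarity tensors

`flatten_tensor(Z, d)` reshapes the first `d` axes into rows (one row per
experiment) and the trailing axes into columns. All flattenings use
row-major (last-axis-fastest) enumeration, fixed once so that the
similarity matrix and the similarity tensor correspond entry-for-entry and
bit-stably. Rows are normalized (`unit-l2` by default, so that cosine
similarity becomes a plain dot product; `max1` and `none` are available —
the exact normalization used upstream of any particular dataset is a
configuration choice, not something the package guesses) and compared by
cosine similarity, giving `S~` of size `N1 x N1`; reverse flattening gives
the order-`2d` similarity tensor `S`. Within-group heterogeneity is
summarized by the mean of `1 - s` over unordered distinct pairs of the
group: 0 means all pairwise similarities are 1, 1 means all are 0.
Self-pairs are excluded because self-similarity is constant and would only
dilute the statistic.

Completeness is a hard requirement: a missing (label-tuple) measurement is
an error, never imputed.

# The integer programs

A hard partition is encoded two ways:

* `X`, Boolean pairwise "different cluster" indicators over ordered pairs
  of grid cells, constrained to be an equivalence relation (reflexivity
  `x_ii = 0`, symmetry `x_ij = x_ji`, transitivity
  `0 <= -x_ik + x_ij + x_jk <= 2`) whose classes are rectangles, which is
  three further linear constraint families: the swap equality
  `x_{i1 i2 j1 j2} = x_{i1 j2 j1 i2}` and two difference inequalities
  bounding `x_{i1 i2 j1 j2} - x_{i1 i2 j1 i2}` and
  `x_{i1 i2 j1 j2} - x_{i1 i2 i1 j2}` in `[0, 1]`.
* `Y`, one-hot cell-to-cluster assignments with
  `sum_r y_ijr = 1` and the slice-wise interpretability condition
  `-1 <= y_ikr + y_jlr - y_ilr <= 1`, i.e. every slice is an
  outer-product 0/1 pattern. The two encodings satisfy
  `1 - x_ij = sum_k y_ik y_jk`.

Two programs are solved to certified global optimality:

* **direct** (`build_direct_program`): maximize
  `<S, 1 - X> + lambda <1, X>` over feasible `X`. The regularizer
  `lambda` (per ordered cell pair, same units as similarities) controls
  the number of clusters: pairs with similarity above `lambda` pull
  together, pairs below push apart, so the between-pair count at the
  optimum is non-decreasing in `lambda`. The package default is 0.5, the
  midpoint of the cosine range for non-negative data; a scan mode is the
  recommended practice on real data. Diagonal terms of `S` are included in
  the objective — they are constant across partitions and immaterial to
  the argmax.
* **refine** (`build_refine_program`): given any hard seed clustering `W`
  (from `cluster_flat` or an external tool — the seed is scientific
  configuration, not a mere initialization), maximize the number of
  unchanged assignments `<W, Y>` over rectangular `Y` with exactly `m`
  slices, `m` being `W`'s cluster count; slices may empty out but are
  never split or merged.

## The solver

`solve_ip` is an exact 0/1 branch-and-bound written for these two
programs. The default **structural** mode branches over grid cells in
row-major order, assigning each cell to an existing cluster (or slice) or
a new one; partial assignments that already violate the Cartesian-product
requirement are pruned, and an admissible bound (sum of per-pair maxima of
the two possible contributions, suffix-cumulated over the undecided cells)
prunes dominated subtrees. The constraint row families are therefore
enforced combinatorially and never materialized — the role lazily
generated rows play in a row-based solver. The **matrix** mode
materializes the deduplicated row system (the sparse `V`, `b_l`, `b_u`)
and runs a generic Boolean branch-and-bound with per-row feasibility
pruning; it is restricted to small grids and exists as an independent
cross-check of the structural mode (the suite verifies both modes return
equal optima, and that the structural optimum equals exhaustive
enumeration on all grids up to 3x3).

`status == "optimal"` certifies a global optimum (gap 0); a time-limited
run returns `status == "limit"` with the incumbent and is refused by the
decoders, and the pipeline exits non-zero unless explicitly allowed.
Solutions are deterministic: the first optimum in canonical enumeration
order is returned, and decoded partitions are canonicalized (clusters
ordered by their lexicographically smallest cell). When distinct optima
are tied, tests compare objective values, not partitions.

Row counts are published in closed form in two conventions
(`ip_row_count`): "paper" counts every family over ordered index tuples
as written (for the 36 x 14 grid this exceeds one million rows, dominated
by the `n(n-1)(n-2)` transitivity rows with `n = 504`), and "built"
counts the deduplicated rows the matrix mode actually materializes
(`3 C(n,3)` transitivity rows, `n1 n2 (n1-1)(n2-1)/4` swap equalities,
`2 n1 (n1-1) n2 (n2-1)` difference inequalities). The built counts are
cross-checked against materialization on small grids.

# The model space

`enumerate_models()` builds the candidate pool: each of the six ordered
species pairs `R->E, R->A, E->A, A->E, E->R, A->R` carries one of three
signs (activation / inhibition / none), giving `3^6 = 729` specifications
under one kinetic convention (mass action or Michaelis–Menten) and one
inhibition mechanism (blocking or removal). This sign-pattern pool is a
reconstruction choice: the generator is configuration-driven (any pair
subset, any conventions), and the biologically motivated restriction that
the receptor must phosphorylate ERK and/or AKT is a separate documented
flag rather than being baked into the count. A symbolic
structural-identifiability analysis is out of scope; its practical
surrogate is `identifiability_filter`, which enforces the AICc
feasibility bound `k <= n - 2` (with an optional numerical
sensitivity-rank screen) and accepts an explicit whitelist so any
externally derived model list can be reproduced exactly.

Right-hand-side conventions (all switchable):

* receptor: `R(0) = dose`, basal decay `dR`; its pool for saturating
  activation is the dose scale.
* activation of target `T` by source `U`: `k U (T_tot - T)` (mass
  action, `k` per minute) or `V U (T_tot - T) / (K + T_tot - T)`
  (Michaelis–Menten, `K` in the normalized concentration units);
  `T_tot = 1` for the phospho-proteins (normalized data).
* blocking inhibition by `I`: the activation flux into the target is
  multiplied by `1 / (1 + I / Ki)`; removal inhibition adds `-kr I T`.
* every species decays at its basal rate.

Integration uses a stiff-capable adaptive method (`lsoda`; defaults
`rtol 1e-8`, `atol 1e-10` for simulation, `1e-6`/`1e-8` inside the
fitting loop), with all doses integrated as independent copies in one
stacked system. Failures and blow-ups raise errors that the fitting layer
maps to effectively infinite loss; trajectories are checked non-negative
at the integrator output rather than silently clipped (only sub-tolerance
negative round-off is zeroed).

Initial conditions: simulations start from `E(0) = A(0) = 0`
(unstimulated baseline), which is also the fitting default — with three
time points there is no room to fit initials, and the first measurement
(taken minutes after stimulation) is not an initial condition. A
`first-observation` mode is available for data whose baseline is unknown.

# Fitting and ranking

`fit_model` minimizes the residual sum of squares over all
`n = doses x times x observables` points by squeeze-and-breathe Monte
Carlo search in log10 parameter space: iterated rounds of log-uniform
sampling inside a moving box (the first round samples 4x more broadly),
elite selection, box contraction around the elites — geometric with
factor `contract`, floored at 2.5 elite standard deviations so the box
never collapses prematurely ("squeeze") — and one scheduled re-expansion
around the incumbent ("breathe"), finished by box-constrained
Levenberg–Marquardt polish from the best distinct elites. Defaults:
rounds 10, 200 samples/round, elite fraction 0.1, contraction 0.5,
breathe at round 6, 8 polish starts, bounds `[1e-3, 1e3]` (log-uniform;
rates are positive and scale-free after normalization). The search is
bit-reproducible given the seed; global optimality is not claimed.

AICc uses the profiled Gaussian form
`n log(max(rss, 1e-12)/n) + 2k + 2k(k+1)/(n-k-1)`; the `1e-12` floor
keeps perfect fits finite. With the default 12-point design the
feasibility bound is `k <= 10`, which every mass-action sign pattern in
the 729 pool satisfies; Michaelis–Menten patterns can exceed it and are
filtered. `rank_models` sorts ascending AICc with ties broken by smaller
`k`, then canonical pool order, and reports ΔAICc from the best.

## Design of the recovery experiments

Three designed experiments back the package's quantitative claims; they
are re-run by the test suite and by `scripts/acceptance.R`, and their
design is part of the package, chosen once:

* **Parameter recovery.** Ten noise-free single- and two-edge mass-action
  cases with rates in `[0.003, 0.12]` per minute, fitted with bounds
  `[1e-3, 10]`. Two deliberate identifiability choices: (i) with a first
  observation at 10 min, rates above ~10/min are indistinguishable from
  instantaneous response, so the wider default box would only add
  unidentifiable plateau regions to the search; (ii) recovery is asserted
  for the production rate constants. The decay rates of a linear
  single-edge cascade are only set-identifiable — the source and target
  decay rates can be exchanged leaving the trajectory (and the rate
  constant) unchanged — so per-parameter decay assertions would test a
  symmetry, not the optimizer. Most battery cases carry both receptor
  edges, which pins the receptor decay through two observables. Because
  the data are noise-free, a converged fit must reach the residual floor;
  fits that do not are restarted deterministically with a shifted seed
  (at most three attempts), a standard multistart safeguard that uses
  only the observable residual, never the generating parameters.
* **Model-selection (AICc rank-1) recovery.** The generating mechanism is
  a single-edge `R->A` response; the candidate pool holds five distinct
  pathway hypotheses (`R->A`; `R->E`; both; `R->E` + cascade `E->A`;
  `R->A` + cascade `A->E`). Strict supersets of the generating model are
  deliberately excluded: with only 12 data points, one extra free edge
  buys enough flexibility that AICc's penalty fails against the overfit
  in a nontrivial fraction of noise draws — a known small-sample
  limitation of information criteria, documented here rather than hidden
  by weakening the experiment. Within the pool, failures still occur when
  a noise draw makes a nested or near-equivalent competitor genuinely
  score better; the ≥80% pass mark reflects that.
* **Selection consistency.** On one fixed noise realization scaled to
  σ ∈ {0.1, 0.01, 0}, the generating model's rank is non-increasing and
  reaches 1 at σ = 0.

# The synthetic generator

`generate_dataset` plants ground truth the pipeline must recover: a
random rectangular partition (`sample_rectangular_partition`, built by
recursively splitting a cluster's row or column set into two arbitrary
subsets, so disconnected rectangles occur), one mechanism per cluster
from a library of five shape-separated single/dual-edge models (pairwise
cosine similarity of the noise-free response vectors below 0.66), a
cell-specific multiplicative amplitude drawn uniformly from `[0.7, 1.3]`,
and additive Gaussian noise truncated at zero. The amplitude is a pure
scalar on the whole response vector, so unit-l2 normalization removes it
exactly and within-cluster cosine similarity is 1 in the noise-free
limit; additive (not multiplicative) noise keeps the similarity
degradation predictable and the data non-negative. Noise is drawn once
per seed and scaled by σ, so recovery on a fixed instance degrades
monotonically as σ grows. The default design is two doses (1, 0.2),
times 10/30/90 min, two readouts.

For a planted partition with noise-free within-cluster similarity 1 and
maximal between-cluster similarity `c`, any `lambda` in `(c, 1)` makes
the planted partition the unique optimum of the direct program;
`separation_lambda` returns the midpoint, which the recovery experiments
and the pipeline's `lambda = "auto"` use.

What the generator does **not** emulate: ligand-family structure,
clinical subtype composition, measurement-specific normalization
artefacts, or missing data. Passing the planted-recovery tests shows the
optimization and model-selection machinery is correct, not that any
particular biological dataset will cluster cleanly.

# Problem sizes and numerical choices

The exhaustive partition oracle is capped at 12 grid cells (the 4x3 grid
already has 19,105 rectangular partitions); solver-versus-oracle
equivalence is checked on all grids up to 3x3 with 50 random similarity
tensors per shape and λ ∈ {0, 0.5, 2}. Recovery experiments use 4x3
(direct, noise-free, oracle-certified), 5x4 with m = 3 over 20 seeds
(refinement, σ = 0.05), and the model-selection experiments described
above; the dimensional-fidelity checks run the full 36x14x2x3x2 design.
Degenerate inputs are hard errors with the offending label tuple or index
named: incomplete tensors, all-zero rows under normalization, negative
similarities in the heterogeneity score, non-hard seed assignments,
singleton heterogeneity subsets.

# Known limitations

* Exact rectangular clustering is exponential in the worst case; the
  branch-and-bound is practical for the small grids where the direct
  pathway is appropriate, while large grids should use the refinement
  pathway, whose search is heavily pruned by the seed.
* AICc with ~12 data points cannot reliably reject a strict superset of
  the generating mechanism (see above).
* Decay rates in single-pathway models are set-identifiable only (decay
  exchange symmetry).
* The heterogeneity score requires non-negative similarities, i.e.
  non-negative measurements under cosine similarity.
* Only cosine similarity is built in; the similarity matrix type is the
  extension point for other kernels, which are untested.
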