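---
title: "Methods and design of the mddpanel pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mddpanel pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mddpanel implements a complete case-control peripheral-biomarker analysis
chain for small transcriptomic cohorts: a negative-binomial
differential-expression screen, network-topology hub consensus, clinical
correlation statistics, and a three-algorithm machine-learning panel with
permutation validation. This vignette is the package's own account of the
statistical machinery: the models and their assumptions, the defaults and why
they are what they are, the numerical corner cases, and what the synthetic
cohorts can and cannot tell you about real data.

## The synthetic cohort generator

Every downstream stage is exercised on cohorts drawn by `generate_cohort()`.
The generator emulates the statistical structure of a 15-vs-15 adolescent
case-control PBMC RNA-seq study:

* **Counts.** Gene counts are negative binomial with variance
  `μ + φμ²`. Baseline means are log-normal with location `log(50)` and scale
  1, a mid-depth bulk profile whose median gene sits near 50 counts and whose
  upper tail reaches the thousands. The default dispersion `φ = 0.1` is a
  typical biological coefficient of variation (~0.32) for human cohort bulk
  RNA-seq. `φ` is shared across genes by default; a named vector overrides
  per gene.
* **The hub plant.** Eight designated genes carry a dichotomous effect:
  SLC4A1, HBB, GYPA and IL6 up in cases, IGF1, CSF2, MMP9 and CXCR1 down,
  each at `|log₂FC| = 3`. The magnitude is chosen so the hubs behave as the
  high-magnitude regulators such screens target — comfortably above either
  conventional fold-change cutoff (1 or 2) at n = 15 per group.
* **Severity coupling.** Each sample has a latent standard-normal severity
  score; its HAMD-17 value is the uniform quantile of that latent on the
  group's range (19–33 cases, 0–6 controls, integer-rounded because HAMD-17
  is an integer scale). Genes named in `gene_hamd_rho` couple their count
  quantile to the severity latent through a Gaussian copula at the requested
  correlation. Defaults plant IL6 at +0.70 and MMP9 at −0.52 — a positive
  and a negative transcript-severity association. Note that the *pooled*
  (cases + controls) sample correlation is systematically larger in magnitude
  than the copula target whenever the gene also carries a group effect,
  because the group separation in both the gene and HAMD contributes shared
  variance. This inflation is intrinsic to pooling two separated groups and
  is why pooled correlation analyses of this design should be read
  cautiously.
* **Demographics.** Ages are uniform integers on 12–17; the sex split is
  near-balanced (ceiling(n/2) males in cases, floor in controls — an 8/7 vs
  7/8 pattern at 15 per group).
* **Protein layer.** ELISA-analogue values are an affine transform of the
  z-scored latent log₂ mRNA signal plus Gaussian noise (sd 0.3 on a unit-2
  slope). A per-gene sign of −1 plants a transcript–protein discordance;
  IL6 defaults to −1 so the discordant-marker scenario is representable.
* **qPCR layer.** The reference gene has Ct ~ N(20, 0.1); target Ct is
  `32 − log₂(μ)` plus N(0, 0.15) noise, one cycle per doubling, so planted
  fold changes are recoverable through `2^−ΔΔCt`.

What the generator does **not** emulate: sequencing reads, alignment
artifacts, batch effects, library-size heterogeneity (columns are roughly
equal by construction), or cell-type composition shifts such as erythroid
contamination of PBMC preparations. Passing tests on synthetic cohorts
therefore validate the statistical machinery, not robustness to those
real-data phenomena.

Determinism: every stochastic function takes an explicit seed and restores
the caller's RNG state; the pipeline derives per-stage seeds from one master
seed, so a rerun with the same configuration reproduces `report.json`
byte-identically.

## Differential expression

Normalization is plain CPM (`count/library size × 10⁶`); FPKM is available
when gene lengths are supplied. There is no TMM or other between-sample
normalization — the screen is aimed at the near-equal-depth case, and
unequal library sizes are handled by scaling to the geometric-mean library
size before the conditional test, which makes the "exact" test approximate
(the scaled group totals are rounded back to integers).

The per-gene test conditions on the gene's total count `t`: under the null
of equal means, the case-group sum is `NB(n₁μ̂, n₁/φ)` against
`NB(n₂μ̂, n₂/φ)` with `μ̂ = t/(n₁+n₂)`, and the two-sided p-value sums the
probabilities of all splits no more probable than the observed one (with a
`1 + 10⁻¹²` relative slack on the probability comparison so ties are counted
despite floating-point noise). At `φ = 0` this degenerates to the exact
binomial split test. Dispersion is the pooled method-of-moments estimate
`φ̂ = max(0, (s² − m̄)/m̄²)`, floored at zero; no empirical-Bayes shrinkage
is applied.

DEGs are genes with `p < p_thresh` **and** `|log₂FC| > fc_thresh`, both
strict. The fold change uses group-mean CPM with a prior count of 0.5 so
all-zero genes are defined (and get log₂FC = 0). The default `fc_thresh = 1`;
2 is an equally supported configuration — both cutoffs are in circulation
for this design, and the default follows the looser screen that feeds the
network stage. P-values are nominal by design (a discovery screen for
high-magnitude regulators that FDR correction would penalize under
inter-individual heterogeneity); `adjust = "BH"` appends adjusted values
without changing the flag.

## Network hubs

The network stage consumes a pre-built edge list (two-column TSV or SIF) —
there is no database retrieval, so analyses are offline and deterministic.
Parsing drops self-loops (with a message) and merges duplicate edges in
either orientation.

Subgraph centrality is the diagonal of the matrix exponential of the
adjacency matrix, computed through the symmetric eigendecomposition
(`SC_i = Σ_j V_ij² e^{λ_j}`); every node has SC ≥ 1 and isolated nodes have
exactly 1. Rankings break ties lexicographically by node id, so top-k sets
are reproducible.

MCODE follows the classic definition: each vertex is weighted by its
core-clustering coefficient (the core number k of the highest k-core of its
closed neighborhood times that core's density); modules grow greedily from
the highest-weight unassigned seed, admitting neighbors whose weight
strictly exceeds `(1 − VWP) × seed weight` with VWP = 0.2 (the conventional
default — the admission is strict, so a VWP of 0 admits only vertices
strictly heavier than the seed's own weight class). Post-processing: an
optional fluff step (off by default) adds boundary vertices with
closed-neighborhood density above 0.2; the haircut (on by default)
iteratively trims members with fewer than two within-module neighbors,
i.e. reduces the module to its 2-core; modules without a 2-core are
discarded. Scores are `density × size`, and each vertex belongs to at most
one module. Because of vertex exclusivity, fluff and haircut monotonicity
(fluff never shrinks, haircut never grows) holds per seeded module, not for
the summed size of all modules.

Consensus hubs are the top-25 centrality nodes intersected with the union of
module members, in centrality order. 25 is the conventional top-node count
for this hub-screening design and is configurable.

## Clinical statistics

* **2×2 tables** use the Yates continuity-corrected χ² with the correction
  clamped (`max(|O−E| − 0.5, 0)`), matching the behavior of base R's
  corrected test; a near-balanced 8/7 vs 7/8 sex table yields exactly 0.
* **Group comparisons** gate on Shapiro–Wilk at α = 0.05 in *both* groups:
  normal-looking data get a Welch (unequal-variance) t-test — the safer
  default when only "independent two-sample t-test" is specified — otherwise
  a two-sided Mann–Whitney U with normal approximation, continuity and tie
  correction (exact enumeration is available but unnecessary at n = 15 per
  group). A group with constant values is treated as non-normal; fully
  constant input returns p = 1 with a warning.
* **2^−ΔΔCt**: `ΔCt = Ct_target − Ct_reference`, referenced to the
  control-group mean ΔCt per gene.
* **Partial Spearman** rank-transforms x, y and every covariate (average
  ranks for ties), residualizes x and y on the covariates by QR least
  squares, and correlates the residuals; p uses the t approximation with
  `n − 2 − k` degrees of freedom. With no covariates this is exactly
  Spearman's ρ. Sex enters as a 0/1 indicator and is rank-transformed like
  any covariate. Constant-after-ranking inputs are an error, not a silent
  NA. The pipeline computes these correlations on the pooled cohort
  (cases + controls) — the design the package targets — with the inflation
  caveat noted above.

## The machine-learning consensus

All three selectors operate on the candidate genes (by default the detected
hubs) as `log₂(CPM + 0.5)` features.

* **LASSO stability selection.** Features are z-scored once; λ is tuned once
  on the full data by leave-one-out cross-validation over the glmnet path
  and held fixed across 100 stratified bootstraps (resampling with
  replacement within each class to that class's size, so both classes are
  always present). The LOOCV rule is `lambda.1se`, the parsimonious choice:
  the deviance-minimizing λ at n = 30 is noisy and routinely small enough to
  admit noise features, which defeats the purpose of a stability filter.
  Fits use convergence tolerance 10⁻⁷; a feature is stable if selected in
  strictly more than 60% of iterations. A caveat worth knowing: a λ chosen
  on the full data does not transfer perfectly to bootstrap resamples —
  duplicated rows inflate sample correlations (SD ≈ 0.2 at n = 30), so when
  the full-data path lives on a very small λ scale (pure-noise data), many
  features can clear a fixed λ inside the bootstraps. Per-iteration
  re-tuning (`retune_per_iteration = TRUE`) removes that artifact at
  roughly a hundredfold cost in fitting time and is off by default.
* **SVM-RFE.** A linear soft-margin SVM (cost 1 — unspecified upstream, so
  the library default) is fitted on standardized features; the feature with
  the smallest squared weight is eliminated (ties eliminate the
  lexicographically larger name), down to one. LOOCV accuracy is computed at
  every subset size with per-fold re-ranking on the training split — the
  leak-free variant — and per-fold standardization; the optimal size is the
  accuracy argmax with ties going to the smaller subset, and the optimal set
  is the head of the full-data ranking. Two consequences of this definition
  at n = 30 deserve emphasis: accuracy has granularity 1/30, and the
  smaller-size tie rule aggressively truncates — when one or two features
  already achieve maximal LOOCV accuracy, the optimal set will not contain
  a third, however real its signal. Exact multi-gene recovery through the
  three-way intersection is therefore intrinsically unstable at this sample
  size; the package documents this rather than papering over it.
* **Random forest.** 2000 CART trees, √p candidate features per split, Mean
  Decrease Gini importance. The default selection rule keeps every feature
  with positive importance — at p = 8 candidates, Gini importance is almost
  never exactly zero for non-constant features, so this rule typically
  passes all candidates through and the intersection is effectively decided
  by the two sparser selectors; `top_k` offers a stricter rule.
* **Panel model and validation.** The consensus panel is the exact three-way
  intersection. The logistic model adds an L2 stabilizer of 10⁻⁴ (not on the
  intercept) via iteratively reweighted least squares, so complete
  separation — routine at n = 30 — yields finite coefficients. The AUC is
  the Mann–Whitney statistic on the in-sample linear scores (ties count
  half). The permutation test refits the same stabilized model on the fixed
  panel under B = 1000 label permutations;
  `p = (1 + #{AUC_perm ≥ AUC_obs})/(1 + B)` with floor `1/(B+1)`
  (≈ 0.000999 at B = 1000). Re-running the full selection per permutation
  would be the stricter design; on the fixed panel the test quantifies the
  overfitting of the *fitted model*, not of the selection.

## Pipeline, configuration, degenerate inputs

`run_pipeline()` sequences simulation/loading → DE → network → clinical
statistics → ML consensus, writing each stage's TSV and a self-contained
`report.json` (parameters, derived seeds, DEG counts, hubs, panel, AUC,
permutation p). Configuration is one flat YAML file; unknown fields and
out-of-range values are reported together with field names; defaults cover
everything. When no edge list is configured, the pipeline simulates an
interaction network over the DEG set with the planted hubs as a dense
clique plus sparse noise edges — synthetic plumbing standing in for a
pre-built interaction subnetwork, clearly not a database snapshot. An empty
consensus panel skips model fitting with a warning rather than failing.

Degenerate inputs are handled explicitly throughout: zero library sizes name
the offending sample; genes with total count 0 get p = 1; empty graphs are
an error for centrality; an all-constant feature can never be selected by
any of the three algorithms; `2^−ΔΔCt` rejects non-finite Ct values.

## Test problem sizes

The test suite validates the machinery at deliberately small scales: 500-gene
null cohorts (20 seeds) for type-I-error calibration of the exact test;
300-gene cohorts for fold-change null behavior; 100-replicate batches for
copula calibration; 20-seed batches for selector recovery and null behavior;
50 runs at B = 200 for permutation-p uniformity; brute-force oracles on
graphs of ≤ 12 nodes, totals ≤ 50, and n ≤ 50 score vectors. These sizes
give tight Monte-Carlo control (binomial SE ≤ 0.05 at B = 100 bootstrap
probabilities, for instance) while keeping the full suite fast.

## Known limitations

* The exact NB test assumes equal effective library sizes after
  geometric-mean scaling; strong depth imbalance degrades its exactness.
* Method-of-moments dispersion is noisy at n = 15 per group; there is no
  shrinkage across genes, by design.
* Pooled-cohort correlation analyses conflate group separation with
  within-group association (documented above).
* Exact recovery of a multi-gene panel via the three-way intersection is
  unstable at n = 30 because of the SVM-RFE tie rule and LOOCV granularity;
  treat panel membership, not panel equality, as the robust output.
* A fixed stability-selection λ does not transfer perfectly to bootstrap
  resamples on null-scale data; the retuning switch exists for when that
  matters more than runtime.
* The permutation test validates the fixed panel's model; it does not
  re-run feature selection per permutation.
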