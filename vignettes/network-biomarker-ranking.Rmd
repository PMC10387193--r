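---
title: "Network-based biomarker ranking: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based biomarker ranking: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`netrank()` scores each gene by a damped, degree-normalised propagation of
phenotype association over a weighted, undirected gene network. With prior
$s_j$ (by default the absolute point-biserial correlation between gene $j$'s
expression and the 0/1 label), symmetric edge weights $m_{ij}$ and weighted
degrees $\mathrm{deg}_i = \sum_j m_{ij}$, the score vector solves

$$ r_j \;=\; (1-d)\,s_j \;+\; d \sum_{i} \frac{m_{ij}\, r_i}{\mathrm{deg}_i}. $$

The reading is a random surfer: with probability $1-d$ the surfer consults
the statistical evidence for gene $j$ directly; with probability $d$ it
arrives from a neighbour, which hands over its own score in proportion to
the edge weight relative to its total connectivity. A gene therefore rises
when it is both associated with the phenotype and connected to other
associated genes, which is exactly the behaviour that distinguishes this
family of methods from per-gene statistics.

Assumptions worth keeping in view: edges must mean "shared biology makes
joint relevance plausible" (confidence-weighted interactions or
co-expression both qualify); weights live in $(0,1]$; the graph is
undirected, so propagation is symmetric; and the prior is nonnegative under
the default convention, which keeps scores nonnegative and the surfer
interpretation intact.

### Solving the fixed point

Iteration starts at $r^{(0)} = s$ and applies the update until the largest
per-gene change drops below `tol` (default $10^{-9}$) or `max_iter`
(default 1000) sweeps have run. Writing the update as
$r \mapsto (1-d)s + dP^\top r$ with $P = D^{-1}M$ row-substochastic, the map
is a supremum-norm contraction with factor at most $d$, so for $d < 1$ the
fixed point is unique, convergence is geometric, and the iteration count is
bounded by $\log(\varepsilon)/\log(d)$ plus a constant — about 30 sweeps at
$d = 0.5$, $\varepsilon = 10^{-9}$. The test suite asserts this bound on
random instances, and `netrank_exact()` provides the independent dense
solve $r = (1-d)(I - dP^\top)^{-1}s$ against which the iteration is checked
element-wise.

Two departures from classical PageRank are deliberate. Isolated or dangling
genes emit nothing and hold $(1-d)s_j$ plus inflow; there is no teleport
redistribution, because the defining equation has none. And neither $s$ nor
$r$ is normalised to sum to one: scores are comparable only within a run,
and the ranking — with ties broken by gene identifier for reproducibility —
is the product. The Jacobi (all reads from the previous sweep) update with a
fixed per-gene summation order makes results bit-identical regardless of how
many workers the update is notionally partitioned across; `workers` is
accepted and validated for interface compatibility but cannot change the
answer.

At $d = 1$ on a disconnected or dangling graph the fixed point can be
non-unique or mass-leaking, so the solver warns rather than refusing.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 0.5 | damping; 0 = pure correlation ranking, 1 = pure connectivity. The default weighs the two evidence sources equally; there is no universal best value, and `compare_rankings()` supports sweeping it. |
| `tol` | 1e-9 | supremum-norm stopping rule; also the yardstick for the solver-vs-closed-form check (10× `tol`). |
| `score_cutoff` | 400 | STRING-style combined-score floor (0–1000 scale), the conventional medium-confidence threshold; weights are `score / 1000`. |
| `beta` | 6 | soft-threshold power for co-expression adjacency `abs(cor)^beta`; `pick_soft_threshold()` chooses the smallest power reaching scale-free fit R² ≥ 0.8. |
| `edge_floor` | 0.01 | sparsification floor for the otherwise complete co-expression graph; raises nothing, only prunes near-zero edges. |
| `k`, `p_cutoff` | 100, 0.05 | signature rule: keep genes with association p below the cutoff, then the `k` best scores (filter, then truncate). |
| `dev_fraction` | 0.7 | stratified development share of samples. |

The association p-values enter selection raw, with no multiple-testing
correction, because the cutoff acts as a coarse relevance gate ahead of the
score ranking rather than as an inference; `select_signature(adjust =
"BH")` switches to corrected values for users who want the stricter gate.

## Design choices where the design was open

**Sign of the prior.** Mixing a signed correlation into a nonnegative
propagation breaks the surfer reading and can produce negative scores, and
down-regulation is no less informative than up-regulation, so the default is
$s = |r|$; `signed = TRUE` is available for exploration.

**Initialisation.** Any start converges for $d < 1$; $r^{(0)} = s$ is exact
at $d = 0$ and closest to the fixed point for small $d$.

**Normalise before or after splitting.** The default normalises per gene on
the full matrix and then splits, matching the natural order of a
preprocessing pipeline; this leaks the test extremes into the scaler, a
caveat worth knowing even though min/max leakage is mild.
`scale_after_split = TRUE` fits the scaler on the development split only and
applies it to both, in which case test values may leave $[0,1]$.

**Per-gene scaling.** Min-max scaling is applied per gene (each gene's range
maps to $[0,1]$), the standard reading of that scaler on a samples × genes
table. Constant genes make the scaler undefined; they map to all zeros with
a warning, which also makes them inert in the correlation and network
stages.

**Co-expression adjacency.** Unsigned, $|c|^\beta$, without the topological
overlap transform by default: unsigned because negative co-expression is
still evidence of shared regulation for ranking purposes, and raw adjacency
because the propagation itself already rewards shared neighbourhoods. The
signed variant and TOM are both available behind flags.

**PCA fitted on the test split.** `evaluate_pca()` fits the components on
the signature-restricted test matrix itself: the question it answers is
"do the selected genes separate unseen samples", not "does a projection
learned on development transfer". The first component's sign is arbitrary,
so the AUC is reported orientation-corrected, `max(auc, 1 - auc)` — which
also means its null expectation sits slightly above 0.5 (about 0.54 at the
test sizes used here), visible in the null-calibration results.

**SVM settings.** The kernel and regularisation are not dictated by the
method; the default is RBF with `cost = 1` and `scale = FALSE` (inputs are
already min-max scaled), recorded in the run report, with a linear preset
one argument away. Class weighting is not used.

**Stratified split.** "Random split" is read as per-label stratification
with `round(fraction × n)` per class; the remainder rule keeps every class
represented on both sides, and a class with fewer than two samples is an
error rather than a silent degenerate split.

## The synthetic generator

`simulate_netrank_data()` exists so that every stage — and the headline
recovery behaviour — can be tested without any external data. It emulates:

- a binary phenotype over `n_samples` with `n_cases` cases;
- correlated gene modules via one latent factor per module: gene $g$ in
  module $m$ is $\lambda z_{m} + \beta_{\mathrm{eff}} y\,[g \in B] +
  \varepsilon$, with $\lambda$ chosen so two module mates correlate at
  `module_cor`;
- a minority of truly associated genes: `n_biomarkers` planted in module 1,
  mean-shifted by `effect_size` noise-SDs in cases;
- a companion network whose edges concentrate within modules
  (`module_density` 0.3 within, `background_density` 0.01 across), with
  edge weights equal to the model-implied expected correlation magnitude of
  the pair plus small jitter, clipped to $[0.02, 1]$.

The defaults — 10 modules, within-module correlation 0.2, unit noise,
densities 0.3/0.01 — were chosen once as a realistic regime for
moderate-strength co-expression modules over a confidence-weighted
interaction graph: module correlations in the 0.2–0.4 range and sparse
cross-module contact are typical of what module-detection methods report on
expression compendia, and the latent-factor form makes every moment
(within-module correlation, case shift, expected edge weight) analytically
predictable, which is what the generator's moment tests assert.

What it does **not** emulate: count-distribution artefacts (data are
Gaussian because the pipeline consumes normalised expression), batch
effects, outlier samples, correlated noise across modules, hub-dominated
degree distributions, or identifier mismatch between network and expression.
Passing the recovery tests therefore demonstrates that the implementation
ranks, selects and evaluates correctly under its stated model — not that
the method will reach the same AUCs on real cohorts.

The reference study condition used by the acceptance checks is 500 genes,
400 samples, 30% cases, 20 planted biomarkers, effect size 1.5, $d = 0.5$,
top-30 signature; null calibration replays it at effect size 0. These sizes
keep a full pipeline run in the low seconds while leaving the planted
signal comfortably recoverable, and the test suite runs the whole battery —
including 20 null replicates — in well under a minute.

## Degenerate inputs and numerical conventions

- Zero-variance genes: correlation undefined → $s = 0$, $p = 1$, warning;
  isolated in co-expression networks. A zero-variance label is an error.
- Perfect correlations: $1 - r^2$ is floored at machine epsilon before the
  t statistic, so $|r| = 1$ yields $p \approx 0$ rather than a division
  error.
- Duplicate edges in either orientation collapse to the maximum weight;
  self-loops are dropped; weights outside $(0,1]$ are rejected.
- Score ties in rankings and signatures break by gene identifier,
  ascending, so output order is a pure function of the input.
- Degenerate connectivity distributions (all degrees equal) make the
  scale-free fit undefined; `pick_soft_threshold()` falls back to the
  conventional power 6 with a warning.
- Floating-point outputs are written at 12 significant digits so that
  regenerated files are stable across runs.

## Known limitations

- The damping factor is a genuine free parameter; rankings at different $d$
  can disagree, and nothing in the data chooses $d$ for you.
- Network and expression must share an identifier universe; there is no
  protein-to-gene mapping layer.
- The dense closed form is a verification tool, guarded to ~2000 nodes; the
  iterative path is the production route and is linear in edges per sweep.
- Evaluation assumes a binary phenotype (one-vs-rest); multi-class
  problems need one run per class.
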