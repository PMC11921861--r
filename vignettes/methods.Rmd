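---
title: "Methods: dual network analysis of music use and emotional symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual network analysis of music use and emotional symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musenet)
```

## The analysis this package implements

`musenet` implements a two-network workflow for questionnaire studies of
music use and emotional functioning.  Ten dimension scores are derived from
four instruments — K10 (anxiety, depression), TAS-20 (DIF, DDF, EOT), RESE
(POS, DES, ANG) and HUMS (HMU, UHMU) — and two nine-node analyses are run,
one per music-use subscale ("healthy" includes HMU and excludes UHMU,
"unhealthy" vice versa):

1. an undirected **regularized partial-correlation network** (RPCN): a
   Gaussian graphical model estimated by graphical lasso over a penalty path
   and selected by EBIC, with node and bridge centrality and bootstrap
   stability diagnostics; and
2. a directed **Gaussian Bayesian network**: hill-climbing structure search
   under a decomposable BIC score, bootstrap arc-strength averaging, and
   ordinary least-squares models for each child node of the averaged graph.

Because respondent-level data from such surveys are typically not
redistributable, the package ships a synthetic-data module whose ground
truth (a sparse precision matrix, or a linear-Gaussian DAG) is known
exactly, so both estimators can be exercised and validated end to end.

## Scale scoring

All items are 5-point Likert responses (1–5).  Scoring is a configurable
sum-score mapping:

* **K10**: anxiety (4 items) + depression (6 items); total 10–50, classified
  10–19 / 20–24 / 25–29 / 30–50 into risk levels 1–4.  The item-to-subscale
  split is not universally printed with the scale; the shipped default
  (anxiety: items 2, 3, 5, 6) is the widely used assignment and is an
  explicit assumption of the package.
* **TAS-20**: facets DIF (7 items), DDF (5), EOT (8); reverse-keyed items
  default to the standard set {4, 5, 10, 18, 19}; total 20–100 classified
  ≤51 / 52–60 / ≥61.  The *dominant facet* is the facet with the highest
  per-item mean; exact ties are reported as all tied facets in the fixed
  order DIF, DDF, EOT.
* **RESE**: three 4-item dimensions (POS, DES, ANG).  Four items at 1–5
  imply the range 4–20, which is what the package enforces (a published
  description giving "5 to 20" is arithmetically inconsistent with four
  items and is treated as a typo).
* **HUMS**: HMU (5 items, 5–25) and UHMU (8 items, 8–40).

Missing responses are rejected by default; listwise deletion and per-item
mean imputation are available behind `na_action`.  Cronbach's alpha uses the
classical variance decomposition `k/(k-1) * (1 - sum(item var)/var(total))`.

## The synthetic cohort generator

The generator emulates the study conditions: 16,588 respondents and the
whole-sample dimension means/SDs (anxiety 7.68 (2.90), UHMU 16.54 (5.94),
…) that `table1_targets()` records.  Three modes share one seeded RNG
stream, so every dataset is bit-reproducible from its config:

* **dimension** mode draws from the zero-mean Gaussian with covariance
  $\Omega^{-1}$, then rescales each column affinely to the target mean/SD.
  The shipped $\Omega$ is a *sparse, illustrative* structure — 10 edges
  (healthy) / 11 edges (unhealthy) with partial correlations of magnitude
  0.15–0.30, qualitatively echoing the published networks (a positive RESE
  clique, the TAS facet structure, a negative DES–Dep edge, a positive
  Anx–Dep edge, and variant-specific music-use edges).  The weights were
  chosen once so that each edge is clearly detectable at the package's
  documented recovery scale (n = 5,000) while the matrix stays comfortably
  positive definite (minimum eigenvalue ≈ 0.4); they are not estimates of
  any empirical network.
* **sem** mode samples a linear-Gaussian structural equation model in
  topological order (child = intercept + Σ coef·parent + noise).  The
  default DAG puts DES upstream, routes distress through Dep to the
  alexithymia facets, and places the music-use node downstream, with all
  |coefficients| ≥ 0.4 so adjacencies are recoverable at moderate n.  SEM
  scores stay on the structural scale — rescaling them would silently change
  the regression truth.
* **item** mode generates Likert items from per-dimension one-factor models.
  Equal loadings are solved from the instrument's target alpha on the latent
  scale ($\lambda^2 = \alpha/(k - \alpha(k-1))$); item latents are cut at
  four thresholds, equal-probability quintiles shifted by a common offset
  solved (by `uniroot`) so the *expected* scale-sum mean equals the target
  exactly.  Consequences worth knowing: discretization attenuates the
  realized alpha below its latent target by roughly 5–10%, and the sum SD is
  a by-product of the alpha target rather than independently calibrated —
  item mode is meant for scoring and reliability checks, while dimension
  mode is the calibrated source for network analyses.  Dimensions are
  generated independently in item mode.

What passing recovery tests on these cohorts does **not** show: real
questionnaire data have ordinal margins, skew, shared method variance and
missingness patterns that the Gaussian/one-factor generator does not
emulate, so recovery rates here are upper bounds on what identical settings
would achieve on field data.

## RPCN estimation

Dimension scores are Gaussianized by the nonparanormal transform: ranks /
n, winsorized to $[\delta_n, 1-\delta_n]$ with
$\delta_n = 1/(4 n^{1/4} \sqrt{\pi \log n})$, mapped through $\Phi^{-1}$ and
rescaled to unit variance.  This is the canonical truncation variant; it is
rank-based, hence invariant to any monotone transform of the raw scores.
Plain z-scoring is also available and the two can be composed.

The graphical lasso solves
$\min_\Omega\; -\log\det\Omega + \mathrm{tr}(S\Omega) + \lambda\|\Omega\|_{1,\mathrm{off}}$
by block coordinate descent (compiled code), warm-starting along a
log-spaced path of 100 penalties from $\lambda_{\max}$ (the largest absolute
off-diagonal correlation, where the graph is empty) down to
$0.01\,\lambda_{\max}$.  Only off-diagonal entries are penalized; we checked
the diagonal-penalized variant and found it substantially degrades
specificity on calibrated synthetic cohorts, consistent with the convention
of the established implementations of this workflow.  Model selection
minimizes $\mathrm{EBIC} = -2\ell(\hat\Omega) + E\log n + 4\gamma E\log p$
with $\gamma = 0.5$ (configurable); ties go to the sparser model.  Edge
weights are the partial correlations
$\rho_{ij} = -\hat\omega_{ij}/\sqrt{\hat\omega_{ii}\hat\omega_{jj}}$.

At the documented recovery scale (n = 5,000 from the shipped sparse truth),
EBIC-glasso retains every true edge, keeps ≥ 90% of true zeros empty, and
estimates nonzero partial correlations with mean absolute error ≈ 0.02.
The residual false edges are tiny (|ρ| < 0.03) — a known property of
single-penalty selection, worth remembering when reading dense empirical
networks.

## Centrality and bridge centrality

Distances use the standard convention $d_{ij} = 1/|w_{ij}|$.  Strength is
the absolute-weight degree; one-step expected influence the signed-weight
degree; closeness the inverse of summed shortest-path distances (0 if any
node is unreachable — the documented convention for isolated nodes);
betweenness uses Brandes accounting with fractional credit split over
equal-length shortest paths, path-length ties compared at 1e-10.

Bridge indices take a community partition — by default instrument
membership: {music use}, {POS, DES, ANG}, {DIF, DDF, EOT}, {Anx, Dep} —
and restrict the same ideas to community-crossing structure.  Bridge
strength and bridge expected influence sum |w| and w over cross-community
edges; bridge closeness is the inverse *mean* distance to nodes outside the
community; bridge betweenness *counts* shortest paths between
cross-community pairs passing through the node (integer counts, matching
the exhaustive-path definition, unlike the fractional credit used for plain
betweenness).  Both raw and z-standardized columns are emitted, since
profile plots of such analyses are conventionally standardized.

## Stability

Edge-weight precision uses a nonparametric bootstrap (resampling rows with
replacement, default R = 1,000) with percentile 2.5/97.5 intervals —
percentile rather than BCa because it is the convention of this workflow
and directly checkable.  Estimator failures inside a replicate are dropped
and counted.

Centrality robustness uses the case-drop bootstrap: for each drop
proportion q in {0.05, 0.15, …, 0.75}, R subsamples of ⌈(1-q)n⌉ rows are
re-estimated and their centrality vectors correlated (Pearson) with the
full-sample vector.  CS(cor = 0.7) is the largest q at which ≥ 95% of
correlations reach 0.7, requiring every smaller q to pass too (so a single
noisy non-monotonicity cannot inflate CS); undefined correlations — e.g. a
constant centrality vector from an empty subsample network — count as
failures.  The grid ceiling 0.75 is the conventional maximum of the CS
scale.

## Bayesian networks

Structure search scores DAGs with the decomposable Gaussian BIC: per node,
the conditional log-likelihood at the OLS fit minus
$\tfrac{k+2}{2}\log n$, counting intercept, k parent coefficients and the
residual variance — the parameter count is stated explicitly because
conventions differ.  Hill climbing evaluates all single-arc additions,
deletions and reversals (acyclicity checked on every candidate), accepts
the best strict improvement, and on ties keeps the first move in a fixed
(parent, child) enumeration order, so search is deterministic given the
seed.  Restarts perturb the incumbent best graph with random legal moves;
the defaults for a single analysis are 50 restarts with 100 perturbations.

Arc confidence bootstraps the rows (size-n resamples, default R = 1,000
for an analysis; package checks use R = 200) and tallies, per unordered
pair, the adjacency frequency (strength) and orientation frequency among
adjacency-containing replicates (direction).  Per-replicate learning uses
one greedy run without restarts: the averaging across replicates, not
per-replicate restarting, is what stabilizes the result, and this keeps the
bootstrap tractable.  The averaged network keeps pairs with strength ≥ 0.85
and orients them when the direction frequency strictly exceeds 0.5; exact
50/50 pairs are excluded and logged rather than arbitrarily oriented.  If
thresholding ever yields a directed cycle, the lowest-strength arc in each
cycle is removed until the graph is acyclic; removals are logged.  Child
nodes of the averaged DAG get OLS models (`lm`) reporting β, SE and t-test
p per parent, plus R², residual standard error and the overall F-test p —
no multiple-testing correction is applied, matching the workflow this
package reproduces.

Because BIC is score-equivalent, a single learned DAG identifies structure
only up to its Markov equivalence class; directions in the averaged network
come from bootstrap orientation frequencies and should be read as
stability statements, not causal proof.

## Numerical choices and degenerate inputs

* Graphical-lasso convergence: relative change of the working covariance
  below 1e-6 of the mean absolute off-diagonal of S; inner lasso sweeps to
  1e-8.  Non-converged path points are excluded from EBIC selection.
* Precision entries below 1e-10 in magnitude are treated as exact zeros
  (coordinate descent produces exact zeros; the cutoff only guards the
  symmetrization average).
* Constant columns are rejected with the column named (z-scoring, edge
  bootstrap); one-row-repeated datasets therefore fail fast rather than
  bootstrapping garbage.
* Singular parent designs score $-\infty$ (structure search) or raise a
  rank-deficiency error naming the child (regressions).
* Hill-climb move acceptance uses a 1e-10 improvement threshold to avoid
  floating-point move cycles.

## Problem sizes used by the shipped checks

The package's own validation suite runs at deliberately reduced replicate
counts chosen to exercise every claim at desk scale: full-size cohorts
(n = 16,588) only for generator calibration; recovery at n = 5,000 with
R = 200 bootstrap replicates; stability behavior at n ≤ 3,000 with
R = 100–200 per drop proportion.  Production analyses should use the
defaults (R = 1,000) that the configuration objects encode.

## Limitations

* The generator's Gaussian margins and independent-dimension item mode are
  idealizations; see above for what that implies about recovery rates.
* EBIC-glasso specificity depends on the sparsity of the true network;
  on dense truths the selected penalty drifts low and small spurious edges
  appear.
* Bootstrap direction frequencies near 0.5 are uninformative; the averaged
  network's exclusions should be inspected via the logged ambiguous pairs.
* The pipeline deliberately implements no group comparisons, moderation or
  mediation analyses.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  variant = "healthy",
  generator = generator_config(n = 2000, seed = 1, mode = "dimension"),
  edge_boot_R = 200, casedrop_R = 100, bn_R = 200)
res <- run_pipeline(cfg)
res$network
head(res$centrality)
res$casedrop$cs
res$bn_avg
write_outputs(res, "musenet_report")
```
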