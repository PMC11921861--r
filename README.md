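# musenet

Dual network analysis of music use, emotion-regulation self-efficacy,
alexithymia, anxiety and depression.

## What this is for

Psychometric studies of how young people use music to regulate emotion
typically measure four instruments — the Healthy-Unhealthy Music Scale
(HUMS: HMU, UHMU), the Regulatory Emotional Self-Efficacy scale (RESE: POS,
DES, ANG), the Toronto Alexithymia Scale (TAS-20: DIF, DDF, EOT) and the
10-item Kessler distress scale (K10: anxiety, depression) — and ask two
complementary questions: *which dimensions are conditionally associated*,
and *which plausibly drive which*. `musenet` packages that workflow for
researchers in psychometric network analysis:

1. **Regularized partial-correlation network (RPCN).** After a
   nonparanormal transform, a Gaussian graphical model is estimated by
   graphical lasso over a 100-point penalty path and selected by the
   extended BIC,

   EBIC(λ) = −2 ℓ(Ω̂λ) + E log n + 4 γ E log p,  γ = 0.5,

   with edge weights the partial correlations
   ρᵢⱼ = −ω̂ᵢⱼ / √(ω̂ᵢᵢ ω̂ⱼⱼ). Node centrality (strength, closeness,
   betweenness, one-step expected influence), bridge centrality across
   instrument communities, bootstrap edge-weight intervals and case-drop
   CS coefficients (CS(cor = 0.7), grid ceiling 0.75) complete the
   undirected analysis.

2. **Bayesian network.** A Gaussian DAG is learned by hill climbing under
   the decomposable BIC score (per node: conditional log-likelihood −
   (k+2)/2 · log n), with 50 restarts × 100 perturbations; 1,000 bootstrap
   resamples are re-learned and arcs kept when they appear in ≥ 85% of
   replicates with a > 50% direction majority. Each child node of the
   averaged DAG gets an OLS model (β, SE, p per parent; R², residual
   standard error, F-test p).

Since respondent-level data of this kind are rarely redistributable, the
package includes a calibrated synthetic generator with known ground truth —
a sparse precision matrix or a linear-Gaussian DAG over the nine analysis
nodes, plus a Likert item mode matched to the published whole-sample
means — so the entire pipeline is testable against truth. Two variants
mirror the study design: *healthy* (HMU, no UHMU) and *unhealthy* (UHMU,
no HMU), nine nodes each.

## Worked example

```r
library(musenet)
cfg <- pipeline_config(
  variant = "healthy",
  generator = generator_config(n = 2000, seed = 1, mode = "dimension"),
  edge_boot_R = 200, casedrop_R = 100, bn_R = 200)
res <- run_pipeline(cfg)

res$network
#> Regularized partial-correlation network: 9 nodes, 12 edges
#>   lambda = 0.03747, EBIC = 49952.12 (gamma = 0.50), n = 2000
```

The selected model keeps 12 of 36 possible edges (the shipped ground truth
has 10; the two extras are weak, |ρ| < 0.03). Centralities on the signed
weighted graph:

```r
res$centrality[, 1:5]
#>   node strength closeness betweenness expected_influence_1
#> 1  HMU    0.299   0.00897           4               0.1032
#> 2  POS    0.571   0.00955           6               0.5708
#> 3  DES    0.608   0.01025           9               0.2739
#> ...
```

DES has the highest strength (0.61) and betweenness (9): it carries the
most absolute edge weight and lies on the most shortest paths — the same
kind of reading one makes of empirical RPCNs. Stability of those orderings
under case dropping:

```r
res$casedrop$cs
#>             strength            closeness          betweenness expected_influence_1
#>                 0.75                 0.55                 0.45                 0.75
```

Strength and expected influence stay rank-correlated ≥ 0.7 (in ≥ 95% of
subsamples) even after dropping 75% of respondents — the scale ceiling —
while betweenness, as usual the least stable index, holds to 45%.

```r
res$bn_avg
#> Averaged Bayesian network: 10 arcs (strength >= 0.85, direction > 0.50)
#>    from  to strength direction
#> 1   Anx Dep        1     0.550
#> 2   DDF EOT        1     0.820
#> ...
#> 10  POS HMU        1     0.685
```

All ten retained arcs are adjacencies of the generating DAG (strength 1.0:
present in every bootstrap replicate); direction frequencies near 0.5 flag
orientations that the data only weakly determine. `write_outputs(res, dir)`
serializes the full bundle (CSV tables, TSV edge list, DOT graph, JSON
manifest with every seed and parameter).

A command-line wrapper with verbs `simulate`, `score`, `ggm`, `centrality`,
`stability`, `bn`, `run` is installed at `inst/cli/musenet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/musenet.R", package = "musenet"))')" \
  run --variant healthy --n 2000 --seed 1 --out report/
```

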