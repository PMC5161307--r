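# caftnmf

Constrained non-negative matrix factorization of functional-marker
abundance matrices from quantitative metagenomics.

## The problem

Shotgun metagenomics reduces a microbial community sample to frequencies of
*functional markers* — KEGG orthology groups or CAZy glycoside hydrolase /
pectin lyase families, each proxying one reaction or hydrolytic capability.
Given an `n x r` samples-by-markers matrix `A`, the goal is to explain
every sample as a mixture of a small number `k` of **combined aggregated
functional traits** (CAFTs): marker-frequency profiles of subcommunity-level
gene-association patterns, shared by all samples in varying intensities.
This is a blind source separation problem,

```
A ≈ W H,   W (n x k) ≥ 0,  H (k x r) ≥ 0,
```

and plain NMF is ill-posed: many factor pairs reconstruct `A` equally well,
most of them biologically meaningless. `caftnmf` restores identifiability
with linear inequality constraints on `H` built automatically from prior
knowledge: a metabolic reaction graph (which markers produce/consume which
metabolites, and which metabolites stay inside cells) and a panel of
reference genomes. For every intracellular metabolite `m` that the panel
supports, the trait rows must satisfy

```
Σ_{j producing m} h_lj ≤ δ1_m Σ_{j consuming m} h_lj      (and/or the converse with δ2_m)
```

collected as `F_Δ Hᵀ ≤ 0`. The constrained, regularized problem

```
min ‖Ã − W H̃‖_F² + α(‖W‖_F² + ‖1ᵀH̃‖₂²)   s.t.  W ≥ 0, H̃ ≥ 0, F̃_Δ H̃ᵀ ≤ 0
```

(`Ã`: column l2-scaled `A`; `H̃`: scaled traits) is solved by multi-start
block-coordinate descent — Nesterov-accelerated projected gradient for the
weight block, augmented Lagrangian with Uzawa iterations for the
constrained trait block. The number of traits `k` and the regularization
`α` are chosen by three criteria computed over a grid: reconstruction
error, bi-cross-validation (Gabriel holdout, unconstrained), and the
concordance of trait matrices fitted on random half-splits of the samples.

The package also ships the marker-aggregation step (domain-hit overlap
resolution, equal dispatch of multi-annotation genes, mean-merging of
multi-KO markers), post-fit geometry-preservation diagnostics, a
planted-trait synthetic generator, and the published fiber-degradation
catalog (86 markers, 43 metabolites, 38 calibrated constraints).

## Worked example

The built-in benchmark: five markers `a`–`e` on a six-metabolite graph, two
planted traits, three reference genomes.

```r
library(caftnmf)

toy <- toy_fixture()
cs <- build_constraints(toy$graph, toy$genomes, toy$thresholds)
cs$F_delta
#>      a  b  c  d e
#> V:1  1 -2  0 -2 0
#> V:2 -2  1  0  1 0
#> X:1  0  1 -2  0 0
#> X:2  0 -2  1  0 0
```

Each row is one inequality on every trait row, e.g. `V:1` says production
of metabolite V may not exceed twice its consumption:
`h_a ≤ 2 (h_b + h_d)`. Metabolite Y is excluded by the classification
rules (a third of the genomes produce it without consuming it; its
consumption side is degenerate).

```r
sim <- simulate_caft_samples(n = 80, noise = 0.2, seed = 42)
fit <- caft_nmf(sim$A, k = 2, alpha = 1e-3, constraints = cs,
                n_init = 5, seed = 7)
fit
#> Constrained NMF fit: 2 CAFTs, 80 samples, 5 markers
#> alpha = 0.001, objective = 0.109455, relative reconstruction error = 0.1492
#> constraints: 4 rows, max violation 0 (tol 1e-06)
#> best of 5 starts (init 3 , iteration cap reached )

round(l1_normalize_traits(coef(fit)), 3)
#>            a     b     c     d     e
#> CAFT_1 0.321 0.000 0.000 0.352 0.327
#> CAFT_2 0.196 0.203 0.213 0.189 0.198

align_traits(coef(fit), toy$H_true)$similarities
#> [1] 0.9992 0.9992
```

The reconstruction error (~0.15) reflects the 20% multiplicative noise; the
two fitted trait rows match the planted ones with cosine similarity 0.999,
including the exact zeros at markers `b` and `c` of the sparse trait — the
result the constraints exist for, since the unconstrained fit reconstructs
the data equally well but aligns worse with the planted traits.
`select_caft_number()` tabulates the three model-selection criteria, and
`distance_preservation(sim$A, fit$W)` checks that between-sample geometry
survives the dimension reduction. A thin command-line wrapper over these
functions is installed at `inst/scripts/caft-tool.R`.

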