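# nmfl21

Robust characteristic-gene selection from nonnegative expression matrices by
L2,1-norm nonnegative matrix factorization.

## The problem

Bulk microarray and single-cell expression matrices are high dimensional
(tens of thousands of genes, a handful of samples), nonnegative, noisy, and
not sparse. Selecting the genes that respond to a condition — abiotic stress
in plants, tumor status in patients — needs a method that (i) respects
nonnegativity, (ii) is robust to outliers and noise, and (iii) produces
row-sparse results so whole genes, not scattered entries, are flagged.

`nmfl21` addresses all three at once. A gene-by-sample matrix
`X` (n × c) is modeled as a nonnegative low-rank background plus a row-sparse
component:

```
min_{Y, E}  ||E||_{2,1} + ||Y||_{2,1}    s.t.   A Y + λ E = X,  U = [Y; E] ≥ 0
```

which is the constrained form of

```
min_Y  ||X − A Y||_{2,1} + λ ||Y||_{2,1}
```

where `||M||_{2,1} = Σ_i ||m^i||_2` (the sum of row Euclidean norms), `A`
(n × d, d < min(n, c)) is a fixed nonnegative basis, `Y` (d × c) the factor
activities, and `E` the scaled residual. The unsquared row norms in the loss
keep outliers from dominating the objective; the L2,1 penalty zeroes entire
rows. Genes whose rows of `E` have large Euclidean norm are the
*characteristic genes*: the ones the low-rank background cannot explain.

The solver is an iteratively reweighted closed-form scheme: with
`B = [A, λI]` and row weights `Q = diag(1 / (2 √(||u^i||² + ε)))`, each
iteration computes

```
U ← Q⁻¹ Bᵀ (B Q⁻¹ Bᵀ)⁻¹ X,   U ← max(U, 0),   Q ← reweight(U)
```

The structured inverse `B Q⁻¹ Bᵀ = A diag(1/q_Y) Aᵀ + λ² diag(1/q_E)` is a
diagonal-plus-rank-d matrix handled through the Woodbury identity, so each
iteration is linear in the number of genes — a full 22810 × 9 chip iterates
in milliseconds.

Also included: top-k gene selection (protocol presets 500 for the plant
analyses, 100 for the tumor analyses), the λ grid-search protocol
(0–1 in steps of 0.1, with 0 floored), exact log-space hypergeometric
term enrichment against GMT gene sets (defaults: max P = 0.01, min overlap
2), a synthetic-data generator with planted characteristic genes, and a CLI.

## Worked example

```r
library(nmfl21)

# 200 genes x 8 samples, rank-3 nonnegative background, 10 planted
# characteristic genes (bumps 5x the median background row norm), 5% noise
sim <- generate_synthetic(n = 200, c = 8, d = 3, k_outliers = 10,
                          outlier_magnitude = 5, noise_sd = 0.05, seed = 0)

fit <- nmf_l21_fit(sim$X, solver_config(lam = 0.3, d = 3, seed = 0))
fit
#> nmf_l21_fit: 200 genes x 8 samples, rank 3, lambda = 0.3
#>   20 iteration(s), converged; smoothed objective 504.22; ||X - AY||_{2,1} + lam ||Y||_{2,1} = 154.365

ranked <- score_genes(fit)          # per-gene ||row of E||_2, sorted
head(ranked, 3)
#>     gene_id    score rank
#> 1 gene_0126 42.56998    1
#> 2 gene_0105 42.45828    2
#> 3 gene_0106 42.43701    3

top10 <- select_top_k(ranked, 10)
mean(top10 %in% sim$truth$outlier_gene_ids)   # precision@10
#> [1] 1

# enrichment of the selection against a toy GMT built from the truth
ann <- simulate_gmt(sim$X, sim$truth, seed = 0)
enrich(top10, ann)[, c("term_id", "k", "n_query", "K", "N", "p")]
#>            term_id  k n_query  K   N            p
#> 1 planted_response 10      10 15 200 1.337579e-13
```

The ranking scores are the Euclidean norms of the sparse-component rows:
all ten planted genes score ~42 while background genes score near zero, so
the top-10 selection recovers the planted set exactly, and the planted
gene-set term is enriched at p ≈ 1.3e-13 (10 of 10 selected genes fall in a
15-gene term over a 200-gene background).

The enrichment statistic is the exact upper-tail hypergeometric probability,
computed in log space; for the published drought-shoot counts (353 of 500
selected genes annotated, background 6617 of 30320) it gives

```r
hypergeom_sf(353, 500, 6617, 30320)
#> [1] 3.473523e-122
```

## Command line

```sh
nmfl21 simulate --genes 200 --samples 8 --rank 3 --outliers 10 --seed 0 \
    --output expr.tsv --truth truth.txt
nmfl21 fit --input expr.tsv --output ranking.tsv --lambda 0.3 --rank 3 --seed 0
nmfl21 select --input ranking.tsv --output genes.txt --top-k 10
nmfl21 enrich --input genes.txt --gmt sets.gmt --output enrichment.tsv \
    --max-p 0.01 --min-genes 2
nmfl21 tune --input expr.tsv --gmt sets.gmt --output grid.tsv --top-k 500
```

The wrapper script is installed at
`system.file("exec", "nmfl21", package = "nmfl21")`; every run writes a JSON
manifest recording the resolved configuration and seed next to its outputs.

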