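---
title: "Robust L2,1-norm factorization for characteristic gene selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust L2,1-norm factorization for characteristic gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmfl21)
```

## The model

A nonnegative gene-by-sample expression matrix $X \in \mathbb{R}^{n \times c}$
is decomposed into a nonnegative low-rank background and a row-sparse
component by minimizing

$$\min_{Y,\,E}\; \|E\|_{2,1} + \|Y\|_{2,1}
\quad \text{s.t.}\quad A Y + \lambda E = X,\; U = \begin{bmatrix}Y\\E\end{bmatrix} \ge 0,$$

where $\|M\|_{2,1} = \sum_i \|m^i\|_2$ sums the Euclidean norms of the rows.
This is the constrained rewriting of the penalized problem
$\min_Y \|X - AY\|_{2,1} + \lambda\|Y\|_{2,1}$: substituting
$E = (X - AY)/\lambda$ turns the loss row norms into $\lambda\|E\|_{2,1}$ and
dividing by $\lambda$ gives the symmetric form. Two properties motivate the
L2,1 norm in both places:

* **Robustness.** The loss charges each gene row its *unsquared* residual
  norm, so a handful of aberrant genes cannot dominate the fit the way they
  do under a squared Frobenius loss.
* **Row sparsity.** Minimizing a sum of row norms is a group-lasso-type
  penalty: whole rows of $E$ (and of $Y$) are driven to zero. A gene either
  carries a coherent signal across samples or is zeroed out as a unit, which
  is exactly the granularity at which gene selection operates.

Genes are scored by $\|e^i\|_2$, the row norms of the sparse component: large
norms flag genes the nonnegative low-rank background cannot explain — the
*characteristic* genes (stress-responsive in the plant protocol,
tumor-associated in the tumor protocol).

### The fixed basis

The basis $A$ (n × d, $d < \min(n, c)$) is drawn once, uniformly on (0, 1)
with the configured seed, and never updated. This follows the published
algorithm, which contains no $A$-update step — only the stacked $U = [Y; E]$
is re-estimated. The source description is genuinely ambiguous here (it calls
$A$ both "basis" and "coefficient" matrix, and says genes are read off the
non-zero entries of $A$ even though $A$ is never touched by the iteration);
we resolve the ambiguity in favor of the algorithm as printed, hold $A$
fixed, and read gene scores from $E$, whose rows are gene-indexed and are
what the L2,1 objective actually makes row-sparse. `score_genes()` exposes
`source = "basis_rows"` for fidelity experiments; with a random fixed basis
it is data-independent and should not be used for real selection.

Because $A$ is random, the background is fitted in the cone spanned by a
random nonnegative basis. For rank-adequate $d$ this is sufficient in
practice: what matters for selection is the *gap* between background rows
(well approximated by some nonnegative combination) and characteristic rows
(far from the cone in every direction). When the true generating basis is
known — as for synthetic data — it can be supplied via `nmf_l21_fit(..., A = )`.

## The algorithm

With $B = [A, \lambda I_n]$ ($I$ is n × n; the identity must live in the gene
dimension for $AY + \lambda E = X$ to type-check) the problem is
$\min_{U \ge 0} \|U\|_{2,1}$ s.t. $BU = X$. It is solved by iteratively
reweighted least squares on the smoothed surrogate
$\sum_i \sqrt{\|u^i\|^2 + \varepsilon}$:

1. $q_i \leftarrow 1 / (2\sqrt{\|u^i\|_2^2 + \varepsilon})$, starting from
   $Q = I$;
2. $U \leftarrow Q^{-1} B^\top (B Q^{-1} B^\top)^{-1} X$ — the closed-form
   minimizer of $\mathrm{Tr}(U^\top Q U)$ over $\{BU = X\}$ (the Lagrange
   multiplier is eliminated analytically and never stored);
3. negative entries of $U$ are projected to zero (the clamp, switchable off);
4. repeat until the relative Frobenius change of $U$ falls below `tol`.

Without the clamp, the alternation provably never increases the smoothed
objective; the package verifies this monotonicity property in its test suite
over seeded instances. With the clamp on, the iteration is a projected
variant: monotonicity is no longer guaranteed in exact arithmetic, so the
tests instead check that the clamped run ends with finite objective and
constraint residual, which is what the method in practice relies on.

### Numerical choices

* **$\varepsilon$ placement.** The printed weight formula puts $\varepsilon$
  inside the row norm, which is dimensionally ambiguous for a vector. We use
  the standard smoothed form $1/(2\sqrt{\|u^i\|^2 + \varepsilon})$, the one
  whose descent property is actually proven in the IRLS literature the
  method builds on. Default $\varepsilon = 10^{-8}$: small enough not to
  distort scores of magnitude $\gtrsim 10^{-3}$, large enough to keep
  weights of collapsed rows at $1/(2\sqrt{\varepsilon}) = 5 \times 10^3$,
  far from overflow. Weights are applied by row division; $Q$ is never
  inverted explicitly.
* **Convergence.** The source says only "until convergence". We stop when
  $\|U_{t+1}-U_t\|_F / \max(1, \|U_t\|_F) < \texttt{tol}$ (default $10^{-6}$)
  or after `max_iter` (default 100) iterations.
* **Objective bookkeeping.** The trace records the smoothed stacked objective
  $\sum_i \sqrt{\|u^i\|^2+\varepsilon}$ — the quantity the iteration
  decreases. The penalized loss
  $\|X - AY\|_{2,1} + \lambda\|Y\|_{2,1}$ (equal to $\lambda$ times the
  unsmoothed stacked objective at feasibility) is reported as a derived
  diagnostic, `objective_eq_loss`.
* **$\lambda = 0$.** $B = [A, 0]$ loses row rank whenever $d < n$, so the
  solver rejects $\lambda \le 0$; the tuning grid maps the protocol's 0
  grid point to a floor of $10^{-3}$.
* **Degenerate rows.** All-zero gene rows are legal input and
  deterministically produce zero rows of $E$ (rank last, in gene-id order).
* **Solvability.** $B Q^{-1} B^\top \succeq \lambda^2 \min_i q_{E,i}^{-1} I
  \succ 0$ for $\lambda > 0$, so the Cholesky solve cannot fail on valid
  input; a failure (possible only on pathological conditioning) raises an
  error naming the ill-conditioned system.

### The fast path

$B Q^{-1} B^\top = A\,\mathrm{diag}(1/q_Y)\,A^\top + \lambda^2\,
\mathrm{diag}(1/q_E)$ is diagonal plus rank $d$. The Woodbury identity
reduces its inversion to one $d \times d$ Cholesky factorization plus
matrix-vector products, so an iteration costs $O(ndc + nd^2)$ and never
materializes an $n \times n$ matrix — a 22810-gene chip iterates in
milliseconds. The dense path (`fast_path = FALSE`) forms $B$ explicitly and
is kept as the reference implementation; tests require the two paths to
agree to $10^{-8}$ relative tolerance up to $n = 2000$.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `lam` | 0.3 | trade-off between the sparse component and the coefficient penalty; 0.3 is the value the published grid search selected for 11 of 12 plant stress datasets |
| `d` | 3 | background rank; must be `< min(n, c)` (warning otherwise) |
| `epsilon` | 1e-8 | smoothing of the row-norm weights (dimensionless, relative to squared row norms) |
| `tol` | 1e-6 | relative Frobenius change of U at which to stop |
| `max_iter` | 100 | iteration cap |
| `clamp` | TRUE | project U onto the nonnegative orthant each iteration |
| `fast_path` | TRUE | Woodbury solve instead of the dense closed form |
| `seed` | 1 | seed of the one-time basis draw; fixes the whole fit |

The λ protocol: `tune_lambda()` fits once per grid value (shared seed, hence
shared basis), selects the top-k genes, applies a user criterion — the
published protocol scored selections by gene-ontology term enrichment, for
which `-log10` of the best `enrich()` p-value is the natural callback — and
returns the criterion-maximizing λ, ties to the smallest. The default grid is
`default_lambda_grid()`: 0 (floored to 1e-3) and 0.1 … 1.0, eleven points.
Selection sizes follow the published protocols via `selection_presets()`:
500 genes per plant dataset, 100 per tumor dataset.

## Enrichment statistic

`hypergeom_sf(k, n_query, K, N)` is the exact upper tail
$P(X \ge k)$ of the hypergeometric law (population $N$, $K$ annotated,
$n_{query}$ drawn): the probability of seeing at least $k$ annotated genes in
the selection by chance. The sum runs over the whole upper support in log
space via `lchoose` and log-sum-exp — no normal approximation — so values of
order $10^{-150}$ and below are representable. `enrich()` applies the
published thresholds by default (raw $p \le 0.01$, overlap $\ge 2$) and
always emits a Bonferroni column (multiplier = number of terms tested)
because the external tool's correction status is not documented; the
background defaults to the union of annotated genes in the GMT and is
configurable, since published background totals vary by analysis and
annotation version. Reported p-values for external annotation services are
therefore reproducible in order of magnitude, not digit-for-digit.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` builds $X = \max(A_{true} Y_{true} + O + N, 0)$:

* $A_{true}, Y_{true}$ uniform(0,1) — a nonnegative background of exact rank
  $d$, representable by the solver's own seeded basis (the generator draws
  $A_{true}$ with the same seeded scheme, so a fit with the same seed and
  rank is automatically "matched");
* $O$: `k_outliers` rows receive an additive nonnegative bump with Euclidean
  norm `outlier_magnitude` (default 5) times the median background row norm —
  mimicking differential expression under stress, not sign-symmetric
  corruption, to stay in the nonnegative regime;
* $N$: i.i.d. Gaussian noise with sd `noise_sd` (default 0.05) times the
  median background entry, truncated at zero by the final clip.

Defaults state a regime where planted rows are unambiguous (5× bumps, 5%
noise); they are scale-free because both magnitudes are relative to the
background. What the generator does **not** emulate: probe-level effects,
correlated noise, library-size differences, mixed outlier magnitudes, or any
gene-ontology structure beyond the toy GMT of `simulate_gmt()` (one term
concentrated on the planted genes, one depleted, random decoys). A green
recovery test therefore establishes that the solver separates a rank-d
nonnegative background from strong additive row outliers under mild noise —
not that it ranks genes correctly on real chips with unknown rank and
structured noise.

## Known limitations

* The basis is never refined; results depend on the seed through $A$. This is
  faithful to the published algorithm but means the low-rank part is a
  projection onto a random nonnegative cone, not a learned NMF basis.
* The clamp makes the iteration a heuristic projection scheme; the descent
  guarantee holds for the unclamped iteration only.
* Enrichment reproduces the statistic, not any specific annotation service:
  term databases, backgrounds and corrections differ across services and
  versions.
* No missing-value handling: input must be complete and nonnegative.
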