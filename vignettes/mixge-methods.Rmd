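---
title: "Set-based mixed-effect tests of gene-environment interaction: model, null distributions, and simulation design"
author: "mixge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-based mixed-effect tests of gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixge)
```

## The problem

Gene-environment (G×E) interaction on a quantitative or binary phenotype is
hard to detect one SNP at a time: per-variant interaction effects are small,
and the multiple-testing burden is severe. Set-based tests pool the SNPs of
a gene (or any biologically meaningful set) into a single test. Two classic
pooling strategies make opposite assumptions:

* **burden-type** tests collapse the set into one weighted score and are
  powerful when per-variant interaction effects are homogeneous in direction
  and size;
* **variance-component** (SKAT-type) tests examine the variance of
  per-variant random effects and are powerful when effects are
  heterogeneous, even with opposing signs.

This package implements a mixed-effect model that embeds both: fixed
interaction effects through a weighted collapse, and per-variant random
interaction effects around them. Two score statistics are derived
sequentially under nested null models so that they are statistically
independent, and their p-values are combined into one significance value.
Because everything is evaluated under null fits (no alternative-model
estimation), the per-set cost is a couple of regressions and one small
eigendecomposition — cheap enough to run at every voxel of an imaging
phenotype.

## The model

For subject $i$ with phenotype $y_i$, covariates $X_i$ (intercept included),
a single environmental exposure $e_i$, and a variant set
$G_i \in \{0,1,2\}^p$ of minor-allele counts:

$$
g\{E(y_i)\} \;=\; X_i^T\beta_x + e_i\beta_e + G_i^T W \pi^{(1)}
 + e_i\, G_i^T W \pi^{(2)} + e_i\, G_i^T \delta ,
$$

where $g$ is the identity (continuous $y$) or logit (binary $y$) link, $W$
is a $p \times q$ weight matrix ($q \ge 1$; the default is the equal-weight
burden vector $1/p$), $\pi^{(1)}, \pi^{(2)}$ are fixed main and interaction
effects of the collapsed set, and $\delta$ is a vector of per-variant random
interaction effects with mean $0$ and variance $\tau^2$ (optionally
$\omega_j\tau^2$ with per-variant weights $\omega$). The null hypothesis of
no interaction is $\pi^{(2)} = 0$ and $\tau^2 = 0$.

## Score statistics and their null laws

The two components are tested sequentially:

1. **Variance component.** Under $\tau^2 = 0$ *with the fixed interaction
   retained*, fit the mean model with design
   $M = [X, E, \text{main}, \mathrm{diag}(E)GW]$ (see below for the main
   block), giving $\hat\mu$ and residuals $r = Y - \hat\mu$. The score
   statistic is the quadratic form
   $S_{\tau^2} = r^T\,\mathrm{diag}(E)\,G\,\omega\,G^T\mathrm{diag}(E)\,r$.
   Its null law is $\sum_i \lambda_i \chi^2_{1,i}$, where $\lambda_i$ are
   the non-zero eigenvalues of $PK$ with
   $P = \hat D - \hat D M (M^T \hat D M)^{-1} M^T \hat D$ the
   variance-projection matrix,
   $K = \mathrm{diag}(E) G \omega G^T \mathrm{diag}(E)$ the interaction
   kernel, and $\hat D$ the diagonal working-variance matrix: the common
   residual variance for the identity link — estimated with the unbiased
   residual-degrees-of-freedom denominator $\widehat{RSS}/(N-k)$, since the
   naive $1/N$ denominator visibly biases the statistic's scale when $k/N$
   is not small (at $N = 200$ with $k = 12$ the bias is 6%, enough to shift
   the whole null p-value distribution) — and $\hat\mu(1-\hat\mu)$ for the
   logit link. The printed projection matrix
   alone does not define the mixture — the kernel must enter — so the
   eigenvalues are computed from the $p \times p$ matrix $B^T P B$ with
   $B = \mathrm{diag}(E)G\,\omega^{1/2}$, which shares the non-zero spectrum
   of $PK$; this follows the standard variance-component score-test theory
   for generalized linear models, and is validated in the test suite against
   direct Monte-Carlo simulation of the statistic under the fitted null.
2. **Fixed interaction.** Under the full null ($\pi^{(2)} = 0$,
   $\tau^2 = 0$; design $V = [X, E, \text{main}]$) the score vector is
   $U = (\mathrm{diag}(E)GW)^T(Y-\tilde\mu)$ with projected covariance
   $\Sigma = C^T\{\tilde D - \tilde D V(V^T\tilde D V)^{-1}V^T\tilde D\}C$,
   $C = \mathrm{diag}(E)GW$, and $U^T\Sigma^{-1}U \sim \chi^2_q$.

The sequential construction makes the two statistics independent, so the
p-values combine by the Fisher rule (4-df chi-square tail at
$-2\log P_{\pi^{(2)}} - 2\log P_{\tau^2}$) or the Tippett rule
($1-(1-\min)^2$). These are the unique combined p-values consistent with
the usual rejection rules at every level $\alpha$, which matters downstream:
FDR adjustment needs continuous p-values, not accept/reject decisions.

A SKAT-style variant (`p_random`) computes the same quadratic form under the
full null instead; it is the interaction analogue of SKAT and is reported
alongside the sequential pair for comparison.

### Genetic main effects: collapsed or per-variant

The model equation adjusts genetic main effects through the collapsed block
$GW\pi^{(1)}$ only. That is the right (and the only feasible) choice when
$p$ is large relative to $N$, as with gene-wide sets of hundreds of SNPs.
But the interaction score tests are derived under the assumption that the
null *mean model is correctly specified*: if true per-variant main effects
are heterogeneous and not spanned by the columns of $GW$ — for instance
effects $(1, 1, -1, -1, 0, \dots)$ whose burden sum is exactly zero — they
remain in the residuals and masquerade as interaction, inflating both
scores far beyond the nominal level. For exactly this reason the
established G×E set tests for small panels adjust every variant's own main
effect in the null model. Both choices are exposed through
`main_effects = c("weighted", "per_variant")` in `fit_null_tau()`,
`fit_null_full()`, `mixge_test()` and `run_voxelwise()`:

* `"weighted"` (default): main block $GW$, as in the model equation —
  appropriate for large sets where per-variant adjustment is infeasible and
  main effects are expected to be weak;
* `"per_variant"`: main block $G$ (one coefficient per SNP) while the
  tested interaction block remains $\mathrm{diag}(E)GW$. The simulation
  engine uses this setting, since its generative models (below) carry
  heterogeneous per-SNP main effects by design. With $p = 8$ and $N \ge
  200$ this costs seven extra degrees of freedom and restores nominal
  type-I error (without it, the empirical size at $\alpha = 0.05$ exceeds
  0.2).

### Evaluating the mixture tail

`mixture_sf()` evaluates $P(\sum_i\lambda_i\chi^2_{1,i} \ge x)$. Equal
weights reduce exactly to a scaled chi-square. Otherwise the default is the
characteristic-function inversion integral of Imhof (1961) via adaptive
quadrature, with the Liu-Tang-Zhang (2009) four-cumulant surrogate as
fallback (quadrature failure, or tails below $10^{-8}$ where absolute-error
quadrature is unreliable) and as an explicit `method = "liu"` fast path for
very large voxel batches. The moment-matching surrogate alone is accurate
near the usual rejection region but can deviate by several percent in the
body of heavily dominated mixtures (one eigenvalue much larger than the
rest) — the package's own Monte-Carlo cross-checks demand agreement within
0.01 everywhere, which only the inversion integral delivers reliably.

### Numerical policies

* Rank-deficient designs are pruned by pivoted QR with relative tolerance
  $10^{-10}$; dropped columns are recorded on the fit object.
* $\Sigma$ is inverted by symmetric pseudo-inverse with relative eigenvalue
  tolerance $10^{-10}$; the chi-square degrees of freedom equal its
  numerical rank. Projected-kernel eigenvalues are kept when
  $\lambda_i > 10^{-10}\lambda_{\max}$.
* Logistic null models are fitted by IRLS (at most 100 iterations, relative
  deviance tolerance $10^{-10}$). A coefficient exceeding 30 in absolute
  value signals (quasi-)separation: an error by default, or — with
  `separation = "prune"`, used by the simulation engine — removal of the
  offending columns and a refit. A quasi-separated adjustment column (e.g.
  a single-carrier SNP whose carrier is perfectly predicted) carries no
  usable information, and a hard error would otherwise abort a
  10,000-replicate stream roughly once per few thousand replicates.
* Perfect fits (residual variance at rounding-noise level), an all-zero
  exposure, or a vanished projected kernel are *degenerate*: the affected
  p-value is 1 with a flag, never an exception.
* P-values are clamped to $[10^{-300}, 1]$ so that log-combination is
  stable.
* Missing genotypes are imputed to the per-SNP mean of observed calls
  (rounding optional); monomorphic SNPs are retained but flagged, and a
  fully monomorphic set is an estimability error.

## The simulation engine

The generative models mirror the published type-I error and power study.
Binary phenotypes follow

$$
\mathrm{logit}\,P(Y_i = 1) = \log\tfrac{0.01}{0.99} + 0.64\,E_i +
\textstyle\sum_{j=1}^{8} a_j G_{ij} + \sum_{j=1}^{8} b_j E_i G_{ij},
$$

with $E_i \sim N(0,1)$ and $G_{ij}$ Hardy-Weinberg at per-replicate MAFs
drawn from $U(0, 0.5)$; subjects are accrued one batch at a time and kept
until the case and control quotas are met (overflow discarded, at most
$10^7$ draws per replicate). Continuous phenotypes drop the intercept (it
models disease prevalence) and add Gaussian noise of variance $\sigma^2$.

Study conditions fixed by `scenario_presets()`:

* **type-I design**: $a = (1, 1, -1, -1, 0, 0, 0, 0)$, $b = 0$;
  small samples are 100 cases/100 controls (200 subjects continuous), large
  samples 1,000/1,000 (2,000 continuous); 10,000 replicates at
  $\alpha = 0.05$ in the headline runs.
* **power designs**: $a_j \sim \mathrm{Bernoulli}(0.5)\times(1 -
  2\,\mathrm{Bernoulli}(0.5))$ redrawn each replicate; $b$ is $C$ times the
  all-ones template (burden), $(1,1,-1,-1,0,0,0,0)$ (variance component;
  zero mean), or $(1,1,0,0,0.5,0.5,0.5,0.5)$ (mixed). Binary designs vary
  $C$ over the published grids (e.g. $\{0.4, \dots, 2\}$ small-sample
  burden, $\{0.05, \dots, 0.25\}$ large-sample burden); continuous designs
  fix $C = 1$ and vary $\sigma^2$ over $\{2, 4, 6, 8, 10\}$ (small) or
  $\{8, 16, 24, 32, 40\}$ (large).

Unstated details decided once: MAFs are floored at 0.005 so that a replicate
cannot draw an essentially empty variant panel; the "200 subjects (100
cases and 100 controls)" continuous-sample description is read as simply
$n = 200$ (case labels are meaningless for a continuous outcome); a
"10,0000 simulations" typo is read as 10,000. The scenario seed spawns one
sub-seed per replicate, so runs are bit-reproducible and chunkable.

What the generator emulates — and what it does not: unlinked variants in
exact Hardy-Weinberg proportions, an exposure independent of genotype, and
homogeneous subjects. Real cohorts add linkage disequilibrium, population
stratification, genotype-exposure correlation and covariate structure, so
passing these simulations shows calibration and power under the stated
sampling models, not robustness to those complications.

## Voxelwise testing and FDR

`run_voxelwise()` applies the test to every column of a subjects-by-voxels
phenotype matrix. Under the identity link all voxel-independent pieces are
shared: the design factorizations, the kernel eigen-structure (per-voxel
eigenvalues are the shared unit-variance spectrum scaled by that voxel's
residual variance), and the $\Sigma$ skeleton. The per-voxel cost is then a
handful of matrix-vector products, which is what makes whole-brain maps
(millions of voxels) tractable. Voxels with zero phenotype variance are
flagged and excluded from the FDR step by default.

Across voxels the chosen combined p-value (Fisher by default) is adjusted
by Storey q-values: $\hat\pi_0 = \#\{p > \lambda\}/(m(1-\lambda))$ with
fixed $\lambda = 0.5$ (the procedure's tuning parameter is otherwise
unstated; a spline-smoother estimate is available via
`lambda = "smoother"`), and step-up q-values
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. A non-positive
$\hat\pi_0$ estimate falls back conservatively to 1, which makes the
adjustment coincide with Benjamini-Hochberg.

## Problem sizes used in the checks

The packaged test suite and the acceptance script size their simulations as
follows (chosen once as the study conditions, with Monte-Carlo tolerances
matched to the replication): 10,000 replicates for the small-sample binary
type-I run and the acceptance script's large-sample run (2,000 in the test
suite's large-sample check, with the binomial tolerance widened
accordingly); 5,000 replicates per configuration for null-uniformity
checks; $10^5$–$10^6$ draws for Monte-Carlo oracles of the mixture tail;
and a few hundred replicates for directional power comparisons, compared at
two Monte-Carlo standard errors.

## Known limitations

* A single environmental exposure; several risk variables must be condensed
  first (`build_environment_pc1()` implements the standardized
  first-principal-component construction, at the cost of the variance the
  first PC does not carry).
* Unrelated subjects; no mixed-model covariance for relatedness.
* The small-sample logit score machinery is mildly anti-conservative at
  $n \approx 200$ with per-variant adjustment: the packaged type-I runs
  measure an empirical size of about 0.06 at $\alpha = 0.05$ (stable across
  seeds, driven by the variance-component score, and unrelated to rare
  variants — it persists when all MAFs exceed 0.2). At $n = 2000$ the size
  is nominal and all four null p-values are uniform. Users with very small
  binary samples should interpret borderline p-values cautiously.
* Burden-style main-effect adjustment (`main_effects = "weighted"`) leaves
  heterogeneous main effects in the residual; see the discussion above for
  when `"per_variant"` is required.
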