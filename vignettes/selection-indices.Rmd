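---
title: "Methods: phenotypic selection indices and heritability for bambara groundnut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic selection indices and heritability for bambara groundnut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bambaraSI)
```

## The problem

Bambara groundnut is a self-pollinating grain legume cultivated almost
entirely from heterogeneous farmer landraces. Pre-breeding for it faces a
specific bind: genetic parameters (genetic variances, covariances, economic
weights) are not available, so an optimal Smith–Hazel index cannot be
constructed. The pragmatic alternative is a *base linear phenotypic
selection index*: subjective integer weights applied to standardized
phenotypes. This package implements that engine, together with the pilot
statistics a pre-breeding study runs around it — trait correlations with a
significance threshold, PCA on the correlation matrix, and broad-sense
heritability from two small-panel designs.

## The selection-index model

Each trait column is converted to standard normal deviate (SND) units,
$z_{ij} = (x_{ij} - \bar{x}_j)/s_j$, so that traits measured in grams,
counts and percentages contribute on a common scale. The scenario score of
a line is $S_i = \sum_j w_j z_{ij}$ over the eleven base traits; emphasised
fatty-acid traits carry weight 3, emphasised yield traits weight 2, all
other base traits weight 1. Because every SND column has mean zero, every
scenario's scores sum to zero over the population: a positive score means
"above the population average in the weighted direction", and roughly half
the population scores positive under any scenario.

Three design points here were genuinely open, and the package exposes each
as a switch rather than deciding silently:

* **Unselected traits at weight 1 vs. excluded.** The engine defaults to
  summing over all eleven base traits with weight 1 on unselected ones
  (otherwise a base weight of one would be vacuous — only weighted-trait
  SNDs would matter); `score_traits = "selected_only"` restricts the sum to
  the emphasised traits.
* **Sample vs. population standard deviation.** Default is the sample
  (n−1) convention appropriate to a 40-line sample of a larger gene pool;
  `sd_type = "population"` switches. Scores are identical up to a common
  positive factor, so rankings never change.
* **Aggregate ranking across an index's scenarios.** An index defines
  several scenarios but one selection is reported per index, so the engine
  ranks lines by the mean of the index's scenario scores
  (`aggregate = "mean"`); `aggregate = "union"` instead takes the union of
  per-scenario top-$k$ sets.

Two further conventions are fixed: *culling is strict* — a line is
eliminated only when a trait falls strictly below its threshold (protein
exactly 15 g/100 g DW survives), with defaults of 15 g/100 g DW seed
protein and 50 % shelling; and *no direction correction* is applied — a
scenario that up-weights linoleic and linolenic acid genuinely selects for
them, and the resulting lipid/yield trade-off is reported, not "fixed".
Culling is applied to the top-$k$ selection step (a hard floor on
advancement candidates), not to the positive-score membership table, which
documents score behaviour alone. Ties in ranking are broken by line
identifier so that output is deterministic across platforms.

Expected gain is computed in original measurement units:
$\Delta_j = 100\,(\bar{x}_{j,\text{sel}} - \bar{x}_j)/\bar{x}_j$. Selecting
the entire population therefore yields exactly 0 % for every trait — a
useful identity the test suite exercises on random fixtures.

## Heritability

Two estimators are provided because a pilot study typically has two kinds
of data, neither large:

* **Parent–offspring regression.** For each generation transition, the
  package regresses offspring on parent values, pooled across lines, and
  reports $100 R^2$. The regression *slope* is the textbook narrow-sense
  estimator and is exposed alongside, but $R^2$ is the quantity this
  pipeline reports; it is sign-blind and invariant to affine transforms of
  either axis.
* **GxE variance components.** The two-way random model
  $y_{ijk} = \mu + g_i + e_j + (ge)_{ij} + \varepsilon_{ijk}$ is estimated
  either by the closed-form expected-mean-squares solution (balanced
  designs; negative solutions truncated to zero and flagged) or by an EM
  algorithm for the REML criterion (any design; components remain
  non-negative by construction). On balanced data with interior estimates
  the two coincide; the tests check agreement to $10^{-6}$ and also
  cross-check the EM fixed point against an independent mixed-model fitter.
  Heritability is $100\,\sigma^2_G/(\sigma^2_G + \sigma^2_{GxE} +
  \sigma^2_{resid})$ — the environment main effect is deliberately excluded
  from the denominator, so the statistic reads as repeatability of genotype
  differences *within* environments, not across them.

Estimators consume plot-level records by default; `use_line_means = TRUE`
collapses to genotype × environment means first, after which the residual
is confounded with the interaction and is reported as zero.

The per-trait summary is the mean of three slots — the two transition
estimates and the GxE estimate — with missing slots contributing zero, and
is additionally rounded half-up to an integer for reporting (computation is
never rounded). Checked against the twelve published per-trait input
triples this convention reproduces eleven of the twelve published summary
values exactly; the pod-dry-weight entry (printed 19 where the rule gives
9) is inconsistent with every combining convention that fits the other
eleven and is treated as a typographical error rather than evidence for a
different rule. The zero-for-missing convention is unusual — statistically
one would average over available slots — but it is the convention the
published summaries follow, so it is the default and the parity test pins
it.

EM-REML convergence: iteration stops when the relative change of every
component falls below $10^{-8}$, capped at 1000 iterations; both the flag
and the iteration count are returned. At the designs used here the EM
typically converges in well under 100 iterations.

## Trait statistics

The correlation module uses Pearson correlation with the $t$-based
critical value $r_\mathrm{crit} = t_{1-\alpha/2,\,n-2}/\sqrt{t^2 + n - 2}$;
at $n = 40$, $\alpha = 0.05$ this is 0.312, which is why missing values are
*refused* rather than pairwise-deleted — silent pairwise deletion changes
$n$ and with it the significance threshold. `drop_incomplete_lines()` is
the explicit opt-in. PCA is the eigendecomposition of the correlation
matrix: component $k$ explains $\lambda_k/p$ of the standardized variance
and loadings are eigenvectors scaled by $\sqrt{\lambda_k}$, with the
largest-magnitude element of each component forced positive so signs are
deterministic across LAPACK builds. The ANOVA helper reports the balanced
least significant difference
$t_{1-\alpha/2,\,df_e}\sqrt{2\,\mathrm{MSE}/r}$; a zero within-group
variance is flagged as the $F \to \infty$, $p \to 0$ limit rather than
reported as a huge noise-driven finite ratio.

## Derived traits

Composition arithmetic uses the standard conventions: crude protein is
nitrogen × 6.25; carbohydrate is computed by difference
(100 − protein − lipid − ash − moisture, all fresh-weight); fresh→dry
conversion is the moisture correction $x \cdot 100/(100 - m)$, the only
dimensionally coherent choice, and its inverse is provided. Single seed
size is total seed weight over seed count in g/seed. Energy fractions use
per-gram factors of 35 (lipid), 14.5 (protein) and 17 (carbohydrate) kJ/g —
one self-consistent set chosen from the several that circulate in the food
literature, and configurable via `composition_constants()`; with these
defaults a high-lipid line at 8 g/100 g lipid, 20 protein, 64 carbohydrate
draws 280/1658 ≈ 16.9 % of its metabolizable energy from lipid.
Carbohydrate-by-difference subtracts exactly the four listed components;
dietary fibre is not subtracted separately.

## The synthetic-data generator

No line-level dataset of this kind is publicly deposited, so the package
ships a generator whose defaults *are* the study conditions the analysis is
built for:

* **Trait panel** — 40 lines drawn from a multivariate normal whose target
  correlation is the published 12-trait between-trait correlation structure
  of the selection-index panel, and whose means and standard deviations sit
  inside the observed gene-pool ranges (lipid 6.4 ± 1.1 g/100 g within
  4.2–8.8; protein 21 ± 3.2 within 14.6–28.9; shelling 55 ± 12 within
  29–81 %; oleic 22 ± 3.5 within 15–29 %; linoleic 39 ± 3 within 33–45 %;
  carbohydrate 64 ± 2.7 within 58.7–70). Yield-trait scales (seed number
  60 ± 20, pod DW 45 ± 15 g, seed DW 30 ± 10 g, seed size 0.55 ± 0.15
  g/seed) are plausible per-plot values for the species. A normal trait
  model matches the approximately normal distributions observed across the
  gene pool. Bounded traits (percentages in [0, 100], weights and counts
  non-negative) are enforced by redrawing violating rows — rejection
  preserves the target correlation where clipping would distort it.
  Rounded published correlation entries need not form a PSD matrix, so the
  generator first clips eigenvalues at a floor of $10^{-8}$ and rescales
  the diagonal; the repair is idempotent and reports its largest
  entry-wise change (for this target the matrix is already PSD and the
  repair is a no-op).
* **GxE trials** — balanced draws from the random two-way model, default
  6 genotypes × 2 environments × 4 blocks, mirroring a pilot
  two-country trial laid out as a randomised complete block design with
  four blocks.
* **Pedigree** — chained generations with offspring
  $= \mu + \sqrt{h^2}(x_p - \mu) + \varepsilon$,
  $\mathrm{var}(\varepsilon) = (1 - h^2)\sigma^2$, so the squared
  parent–offspring correlation equals the planted $h^2$ in expectation and
  the variance is stationary across generations; default 6 lines over
  three generations.

Every generator takes one integer seed, expanded internally into
per-purpose streams so that adding a generator never shifts another's
output, and the caller's RNG state is always restored.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: multivariate normality (real trait panels are
skewed, bounded and occasionally bimodal across geographic subgroups),
genotype-specific environmental response beyond a single interaction
variance, year effects and carry-over in the pedigree (the synthetic
pedigree is a pure autoregression), measurement error structure, and any
genetic linkage between traits — the correlation structure is phenotypic
only.

## Problem sizes and numerical checks

The test suite exercises recovery at the sizes where Monte-Carlo noise is
small relative to the claims: correlation recovery at 5000 lines (max-abs
tolerance 0.05), heritability recovery at 10 000 pairs (±3 points on a
planted 60 %), and variance-component recovery as the mean of 200
replicates of a 50 × 10 × 4 design (within 5 % of truth). Oracle
equivalence (scores, culling, compilation, gain, correlation, ANOVA F
against brute-force recomputation) is checked at $10^{-10}$–$10^{-12}$ on
10-line fixtures. Degenerate inputs are errors, not silent results:
constant trait columns (standardization and correlation undefined),
all-missing heritability slots, zero population trait means in gain
reports, empty selections.

## Known limitations

* The membership and gain tables of any real study depend on its raw
  line-level data; with synthetic panels the package reproduces the
  *procedure* and its identities, not any particular published membership
  or gain value.
* The EMS estimator requires balance; unbalanced trials must use EM-REML,
  which is slower and, near a zero-variance boundary, converges only
  linearly.
* Weights are subjective integers by design; nothing in the engine
  estimates them, and no economic or genomic index is provided.
* Percentage traits are validated to [0, 100] but compositional closure
  (components summing to 100) is only enforced where a formula implies it.
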