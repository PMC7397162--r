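---
title: "Recommender-based genomic selection: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommender-based genomic selection: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(ibcfgs)
```

## The prediction problem

Multi-environment breeding trials produce a lines-by-"items" table, where an
item is one trait measured in one site-year (`GY_LND_2015`, `HD_PUL_2017`,
...). The table is always incomplete: lines are dropped, seasons fail,
new candidates have no records at all for an upcoming environment. ibcfgs
treats this as a recommender problem — lines are users, trait-environment
combinations are items — and fills missing cells by item-based collaborative
filtering (IBCF).

### The IBCF predictor

Each item $j$ is standardized over its observed cells,

$$Z_{ij} = \frac{y_{ij} - \mu_j}{\sigma_j},$$

where $\mu_j$ and $\sigma_j$ are the observed-cell mean and the
**population** (divide-by-$n$) standard deviation. The population
convention matters: it is the one that reproduces the method's published
worked example, where a four-value column with spread 0.2795 is reported as
0.28 (the $n-1$ convention would give 0.32).

For a missing cell $(i, J)$ the standardized prediction is the
absolute-weight-normalized weighted average of the line's observed items,

$$\hat z_{iJ} = \frac{\sum_{j' \in N_i(J)} z_{ij'}\, w_{Jj'}}
                     {\sum_{j' \in N_i(J)} |w_{Jj'}|},
  \qquad
  \hat y_{iJ} = \mu_J + \sigma_J\, \hat z_{iJ},$$

with $w_{Jj'}$ the pairwise-complete Pearson correlation between items $J$
and $j'$ and $N_i(J)$ the set of items observed for line $i$. Using *all*
observed items as the neighborhood (no top-$k$ truncation) is the default:
it is the only choice that reproduces all four worked-example predictions.
`top_k` and `min_abs_weight` are exposed for experimentation. Undefined
similarities (fewer than two complete pairs, or zero variance among them)
get weight 0; a cell whose weights sum to zero falls back to $\mu_J$ and is
flagged rather than silently reported.

Because the predictor is a bounded weighted average of standardized
neighbors ($|\hat z_{iJ}| \le \max_{j'} |z_{ij'}|$), it cannot extrapolate
beyond the line's own record range — a feature (robustness) and a
limitation (no transgressive predictions). IBCF is not model-based: it
estimates no variance components and provides no uncertainty statements.

## Cross-validation scenarios

Four evaluation designs mirror how the approach is used in a breeding
program:

* **Multi-environment** (`scenario_multi_env()`): random partitions (by
  default 10 partitions, 25% of lines in the test set, drawn
  *independently* per partition so test sets may overlap across
  repetitions); the target items' cells of the test lines are masked,
  everything else stays observed. Masking only the target cells is
  deliberate: the test lines must keep records on other items or the
  recommender has no neighbors.
* **Next season** (`scenario_next_season()`): the target trait's test-year
  columns are masked *for every line* and predicted from earlier years and
  the other traits. A fully masked column has no observed cells, so its
  mean, SD and similarities are necessarily computed from the full table
  before masking — the behavior of the reference workflow this scenario
  reproduces. This makes it an *evaluation* design, not a deployable
  forecast, and it carries an intrinsic optimism under the null: the
  weights are estimated from the same lines that are scored, which inflates
  the null predictive ability by roughly $\sqrt{k/n}$ (about 0.11 for
  $n = 150$ lines and $k = 3$ neighbors). The package therefore runs null
  calibration checks on the multi-environment design, whose held-out-line
  masking is leakage-free, and documents the next-season bias here instead
  of hiding it.
* **Secondary traits** (`scenario_secondary()`): grain yield is predicted
  from sets of spectral indices (NDVI, NWI-1, SR, their pairs, all three);
  only the target and the set's items enter the table.
* **Marker-adjusted IBCF** (`scenario_marker_ibcf()`): the two-step design
  described next, with 10 partitions and 20% test lines by default.

Metrics are computed per partition and then averaged (mean ± SE =
sd/$\sqrt{n_\text{partitions}}$), never pooled: predictive ability is the
Pearson correlation between predicted and observed values; MAAPE is the
mean arctangent absolute percentage error
$\text{mean}\,\arctan|{(y - \hat y)}/{y}|$, bounded in $[0, \pi/2]$ and
taken as $\pi/2$ when $y = 0$ (and 0 when both are 0); RMSE is in trait
units. MAAPE is named but not defined in much of the applied literature; we
use the Kim–Kim definition above.

## Bayesian whole-genome regression

IBCF cannot consume marker data directly, so genomic information enters by
*trait adjustment*: each item is regressed on all markers
(`Trait ~ Markers + Error`), every cell is replaced by the line's genomic
estimated breeding value $\hat\mu + M\hat\beta$, and IBCF runs on the
adjusted (now complete) table. Five marker-effect priors are implemented in
a single Gibbs framework (`fit_wgr()`), with the per-marker scan in
compiled code:

| model  | prior on $\beta_k$ |
|--------|--------------------------------------------------|
| BRR    | $N(0, \sigma_b^2)$, common variance |
| BayesA | $N(0, \sigma_k^2)$ per marker, scaled-inv-$\chi^2$ variances |
| BayesB | spike at 0 (prob. $1-\pi$) + per-marker-variance slab |
| BayesC | spike at 0 + common-variance slab |
| BL     | double-exponential via exponential mixture of normals |

Hyperprior constants follow the standard scale-matching recipe: all
scaled-inverse-$\chi^2$ priors use 5 degrees of freedom, with scales chosen
so that a priori the residual variance mode is $(1-R^2)\,\mathrm{var}(y)$
and the markers jointly explain $R^2 = 0.5$ of the phenotypic variance
(configurable). The spike-slab inclusion probability has a Beta prior with
mean 0.5 and weight 10; the Bayesian LASSO's $\lambda^2$ has a Gamma prior
(shape 1.1) with prior mean $2\,\mathrm{MS}_x (1-R^2)/R^2$. Inverse-Gaussian
draws for the LASSO's $\tau_k^{-2}$ use the Michael–Schucany–Haas
transformation. Default chain settings are 20,000 iterations, 15,000
burn-in, thinning 5; every sampler is exactly reproducible given
`mcmc_settings(seed = )`.

Numerical guards: marker columns are mean-centred (centring stored and
reapplied at prediction); prior variances are floored at $10^{-12}$;
$\tau^2$ is clamped to $[10^{-10}, 10^{10}]$ and the inverse-Gaussian mean
to $10^8$ to keep the LASSO updates finite when an effect collapses to
zero. Because the Gibbs scan is sequential, permuting marker columns
changes the chain realization; posterior means agree up to Monte-Carlo
error, and that is what the tests assert.

Two leakage policies are exposed for the marker-adjusted scenario.
`"strict"` (default) refits the per-item regressions inside each partition
on training lines only, so no test-line phenotype is read before
evaluation — verified in the tests by poisoning the held-out cells with
sentinels and checking the predictions are bit-identical. `"package"`
adjusts once on all lines before masking, reproducing the workflow this
scenario emulates; its results are flagged with the mode used.

Ordinal disease scores (0–9 snow-mold type scales) are treated as Gaussian
in the regressions, matching the emulated workflow; this is a documented
mismatch, not an endorsement.

## GBLUP baseline

The comparison model is univariate GBLUP, $y = 1\mu + g + e$ with
$g \sim N(0, \sigma_g^2 K)$: VanRaden method-1 relationship matrix
$K = WW'/(2\sum_k p_k(1-p_k))$, REML by a single eigendecomposition of $K$
and one-dimensional optimization over
$\lambda = \sigma_g^2/\sigma_e^2$ (log-scale search on $[-14, 14]$ with the
boundary candidates also evaluated), BLUP breeding values
$\hat g = \sigma_g^2 K V^{-1}(y - 1\hat\mu)$, and repeated disjoint 10-fold
cross-validation (`gblup_cv()`), in contrast to the IBCF scenarios' random
overlapping partitions. A $10^{-6}$ diagonal jitter keeps $K$ numerically
positive semi-definite (jitter 0 is available, e.g. for exact-equivalence
checks against the ridge-regression marker solution, which holds at
$10^{-6}$ tolerance). Predictions for unphenotyped lines flow through the
relationship matrix blocks.

## What the synthetic generator emulates — and what it does not

`simulate_genotypes()` / `simulate_phenotypes()` emulate the panel the
method was developed on: by default 456 lines × 15,229 biallelic SNPs with
allele frequencies uniform on (0.05, 0.5), and grain yield / heading date /
plant height over nine site-years (Lind 2015/17/18/19, Pullman 2015–19).
Trait profiles are realistic constants — GY 4 ± 0.6 t/ha ($h^2$ 0.4), HD
160 ± 3 Julian days ($h^2$ 0.8), PH 85 ± 8 cm ($h^2$ 0.7) — and nothing
downstream depends on the means, only on correlations and heritability.
The default between-environment genetic correlation is 0.2, chosen once to
sit inside the 0.08–0.31 range of average between-environment correlations
reported for this crop system.

The generator's key structural choice: between-environment correlation is
imposed on the *QTL effects* (rows of the effect matrix are jointly
Gaussian with correlation $\rho_G$), not on residuals, because shared
genetic signal across items is exactly what IBCF exploits. Residuals are
orthogonalized against the genetic values and rescaled so the realized
$\mathrm{var}(g)/\mathrm{var}(y)$ equals the requested $h^2$ *exactly*,
which makes heritability-recovery tests sharp. Secondary spectral traits
are generated at a target genetic correlation with yield (defaults follow
the reported field values: +0.12 NDVI, −0.13 NWI-1, +0.11 SR) and ordinal
scores by quantile thresholding of a latent value.

Not emulated: linkage disequilibrium and genetic maps (markers are
independent), augmented field designs and spatial effects (inputs are
assumed to be BLUEs/BLUPs), genotype-by-environment interaction beyond the
correlated-effects structure, and weather. Consequently, passing tests
show that the algorithms are correct and well-calibrated under the assumed
statistical structure — they do not certify accuracy levels on real trials,
where LD, G×E and design effects move the numbers.

## Problem sizes used by the test suite

The statistical checks run at desk scale, chosen so the whole suite
finishes in a couple of minutes while keeping every assertion sharp:
IBCF oracle checks on 10 × 6 tables; GBLUP–RRBLUP equivalence at
$n \le 50$, $p \le 100$; heritability recovery at $n = 500$, $p = 800$
over 20 seeds; Gibbs sampler validation at $n \le 400$, $p \le 400$ with
1,200–6,000 iterations (50,000 for the fixed-variance ridge equivalence);
scenario trend and null calibration at 120–150 lines over 20 seeds. The
full 20,000/15,000 chain settings remain the user-facing defaults.

## Known limitations

* The similarity matrix is estimated, never shrunk; with few lines the
  weights are noisy, and the next-season design's in-sample weights are
  optimistically biased under the null (quantified above).
* Items observed on disjoint line sets get an undefined (zero) weight
  rather than an imputed one.
* No multivariate (joint multi-trait) Bayesian models, no frequentist
  LASSO, no matrix-factorization recommenders, and no convergence
  diagnostics beyond kept-sample counts; these are explicit non-goals.
* VCF/PLINK/HapMap parsing is out of scope: inputs are delimited 0/1/2
  tables.
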