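---
title: "Replication-fingerprint drift scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication-fingerprint drift scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdrift)
```

## Scientific problem

Somatic cells accumulate DNA methylation changes as they divide. A
longitudinal passaging experiment — one cell line profiled repeatedly
across cumulative population doublings (cPD) — records this
*replication drift* directly, but it also records everything else that
accumulates with time in culture: media adaptation, clonal selection,
batch drift. Any predictor trained on a single passaging series is
therefore confounded: a CpG can track cPD because replication drives it
or because culture does.

`methdrift` implements a pipeline that separates the two using a second,
in-vivo dataset (e.g. an aging-tissue cohort profiled on the same
platform). The key observation: replication-driven comethylation
modules must reproduce in tissue, where cells have also divided, while
culture artifacts have no in-vivo counterpart. The pipeline is:

1. **PC clock.** Principal components of the training beta matrix
   (CpG-centered, unscaled, all `min(n, p)` components kept), with an
   elastic net over component scores against cPD (`fit_pca()`,
   `fit_pc_clock()`). Component-score regression is far better
   conditioned than CpG-level regression when `p >> n`.
2. **Driver CpGs.** Per-CpG importance aggregates z-normalized absolute
   loadings over active components, each weighted by the component's
   contribution to the predicted score, `|coef_k| * sd(score_k)`
   (`select_driver_cpgs()`).
3. **Consensus network.** Biweight midcorrelation between CpGs, soft
   thresholded to an adjacency (`|r|^power`, default power 6),
   transformed to topological overlap (TOM), computed in both datasets;
   the consensus is the elementwise minimum after quantile-matching the
   second TOM to the first (`bicor_matrix()`, `adjacency()`, `tom()`,
   `consensus_tom()`). Average-linkage clustering of `1 - TOM` with a
   static cut (`cluster_modules()`) yields modules; eigengenes and kME
   summarize them (`module_eigengenes()`, `kme()`).
4. **Module selection.** A per-module PC clock is fit in the training
   series; a module is kept only if its clock generalizes both to an
   independent passaging series (*in vitro*) and to the tissue cohort
   against age (*in vivo*), Pearson r at least `r_min = 0.5` in both
   (`fit_module_clocks()`, `select_modules()`).
5. **Composite score.** The selected modules' per-module PC scores are
   pooled into one design matrix and a single elastic net is fit against
   cPD (`fit_composite()`, `score_composite()`), with a provenance map
   from every pooled component back to its module.
6. **Evaluation.** Covariate residualization by OLS (`residualize()`),
   Kruskal–Wallis group tests (`group_test()`), Pearson correlation
   (`correlate()`), and per-SD Cox proportional hazards
   (`cox_hazard()`), dispatched over standard study designs by
   `run_design()`.

## Model and conventions

Beta values are constrained to `(0, 1)`; all latent structure in the
generator and all linearity assumptions live on the M-value scale,
`M = log2(beta / (1 - beta))` (`logit2()`, `expit2()`). Cumulative
population doublings follow `cPD = log2(final / initial)` summed over
passages (`compute_cpd()`, `cumulative_cpd()`), which makes cPD exactly
additive across consecutive passages.

The biweight midcorrelation of two CpG profiles downweights samples far
from the median: with `u = (x - med(x)) / (9 mad(x))` and weights
`w = (1 - u^2)^2` for `|u| < 1` (0 otherwise), it is the Pearson
correlation of the weighted median deviations. A profile with zero MAD
falls back to Pearson; a constant profile gets zero correlation with a
warning.

Topological overlap for adjacency `a` is
`w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
`l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu` (off-diagonal sums):
two CpGs overlap when they share neighbors, not merely when they
correlate, which stabilizes module boundaries under noise.

`cluster_modules()` applies a *static* cut: `cutree()` at
`cutHeight = 0.95` on the average-linkage dendrogram of `1 - TOM`,
discarding clusters below `minClusterSize = 50` (label 0 =
unassigned). A `deepSplit` argument is accepted and recorded for
provenance, but no hybrid dynamic refinement is performed; the
package's defaults and fixtures are chosen so that recovery does not
hinge on such refinements. Module labels are integers by decreasing
size.

Eigengenes are the first principal component of the z-scored module
rows, scaled to unit sample variance and signed so the mean kME of the
module's members is non-negative. `top_kme()` ranks hub CpGs by
`|kME|`, since modules deliberately mix CpGs that gain and lose
methylation along the same factor.

All elastic nets use `alpha = 0.5` and choose the penalty at the
minimum mean 10-fold cross-validated squared error, with the fold
assignment drawn deterministically from a seed. Numerically constant
score columns (the degenerate trailing component implied by centering)
are excluded from the fit and restored as zero coefficients, so pooled
coefficient vectors keep their full advertised length
(`n_train * n_selected_modules`; 62 at the default problem size).

## What the synthetic generator emulates

`sim_config()` freezes a problem size modeled on a realistic study: 31
training samples spanning 43–75 cPD, an 85-sample tissue cohort aged
23–83, two physiological and two artifact modules of 60 CpGs each, and
280 background CpGs. On the M scale a module CpG is

```
m = mu + lambda * f + gamma * h + noise
```

where `f` is the module's primary driver — `slope * cPD` for
physiological modules in vitro and `slope * age` in vivo; a latent
factor correlated 0.8 with cPD *in vitro only* for artifact modules —
and `h` is a module-specific coherence factor (SD 0.6, per-CpG weights
0.5–1.5, sign shared with the drift loading), drawn orthogonal
in-sample to the drift covariate and to the other modules' factors.
The coherence factor encodes that real comethylation modules cohere
beyond their drift association; without it, all drift-driven CpGs would
form a single rank-1 block and distinct modules would be
mathematically unidentifiable from the data. The orthogonalization
removes finite-sample luck from module identity.

The generator does **not** emulate probe-level measurement error
models, cell-composition mixtures, genomic autocorrelation along
chromosomes, or non-linear drift trajectories; it is a ground-truth
harness for the pipeline's statistical machinery, not a biological
simulator. Downstream cohorts (`simulate_cohort()`) key group
membership, survival hazard, or per-tissue means to the planted drift
factor so evaluation statistics have known answers.

## Worked run

```{r pipeline}
cfg    <- sim_config(seed = 42)
train  <- simulate_passaging(cfg)
tissue <- simulate_tissue(cfg, train$truth)
val    <- simulate_passaging(cfg, seed = 542, n = 14,
                             sample_prefix = "val", truth = train$truth)

cons <- consensus_tom(tom(adjacency(bicor_matrix(train$beta))),
                      tom(adjacency(bicor_matrix(tissue$beta))))
part <- cluster_modules(cons)
part$sizes

clocks <- fit_module_clocks(train$beta, train$sheet, part, seed = 42)
sel <- select_modules(clocks,
                      list(beta = val$beta,    sheet = val$sheet),
                      list(beta = tissue$beta, sheet = tissue$sheet))
sel$correlations

comp <- fit_composite(train$beta, train$sheet, part, sel$selected,
                      seed = 42)
cor(score_composite(comp, val$beta), val$sheet$cpd)
```

The artifact modules never survive the consensus: their CpGs are pure
noise in tissue, so their cross-dataset topological overlap collapses
and they stay unassigned at the static cut — and even when handed to
`select_modules()` directly, their clocks fail the in-vivo hurdle.

## Numerical choices and limitations

* PCA keeps every component, including the degenerate trailing one, so
  score matrices have a fixed, predictable width; degeneracy is handled
  at the elastic-net stage, not by silently truncating the basis.
* Model archives are JSON with doubles written at 17 significant
  digits, so `load_model(save_model(m))` predicts bit-identically
  (`save_model()`, `load_model()`); unknown schema versions are an
  explicit error.
* `bicor_matrix()` requires at least 4 samples — median-based weights
  are meaningless below that.
* The static cut is deliberately simple; very unequal module sizes or
  heavy overlap between modules would call for dynamic tree cutting,
  which this package does not implement.
* `select_modules()`'s `r_min = 0.5` is a screening threshold, not an
  inference; downstream claims should rest on the evaluation functions,
  with covariates residualized out first.
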