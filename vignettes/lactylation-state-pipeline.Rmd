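---
title: "Methods: consensus lactylation scoring and state discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus lactylation scoring and state discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
the reasoning behind every tunable default and numerical convention. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The problem and the model

Lactylation activity cannot be measured directly in transcriptomic data;
the package proxies it by the coordinated expression of a curated
lactylation-related gene (LRG) signature. Because any single gene-set
scorer has characteristic biases — sensitivity to the top of the ranking,
to signature size, to expression magnitude — five algorithms with
different mechanics are run side by side and fused. Four are pure rank
statistics (AUC recovery curve, rank-U, mean rank, weighted running sum)
and one is an expression contrast against bin-matched controls. All
per-cell ranks are descending with average ties, so the rank scorers are
deterministic and invariant under any strictly monotone transformation of
a cell's expression; the canonical AUC implementation breaks ties
randomly, which we deliberately avoid for testability.

The consensus is the unweighted mean of the five min–max-normalized
scores. How five heterogeneous scores should be fused is genuinely open;
a mean is the simplest exchangeable choice, `fusion = "median"` is
exposed as the obvious robust alternative, and min–max normalization
absorbs the scale differences (notably the unbounded running-sum score).

### The quartile rule

Cells below the consensus's 25th percentile are the low lactylation state
(LLS), cells above the 75th the high state (LHS), the rest the dynamic
transition state (LDTS). Two conventions needed fixing:

- **Quantile definition.** R's default order-statistic interpolation
  (type 7) is used. With all-distinct scores and n divisible by 4 the
  interpolated quartiles fall strictly between order statistics, so the
  strict inequalities put exactly n/4 cells in each tail — the property
  the construction is meant to have — and in general the tails hold
  ⌊n/4⌋ or ⌈n/4⌉ cells.
- **Boundary ties go to LDTS** (strict inequalities on both sides),
  matching the below/above wording of the rule; a fully tied consensus
  therefore yields 100% LDTS, with a warning, rather than an arbitrary
  split. Fewer than 8 non-missing cells is an error: quartiles of fewer
  points are not meaningful strata.

## Stage parameters

| Stage | Parameter | Default | Rationale |
|---|---|---|---|
| QC | min cells per gene | 5 | standard gate; genes below are uninformative noise |
| QC | detected genes per cell | [200, 7000] inclusive | low = empty droplets, high = doublets |
| QC | mitochondrial fraction | > 0.20 removed (strict) | dying-cell signature; `MT-` prefix |
| HVG | count / bins | 2000 / 20 | classic binned standardized dispersion |
| PCA | components | 20 | the variance relevant to state structure |
| Clustering | resolution / k | 0.8 / 20 | Seurat-equivalent SNN + Louvain defaults |
| Scoring | AUC top fraction | 0.05 | the recovery curve's canonical integration window |
| Scoring | rank cap r_max | 1500 | past this depth, ranks carry dropout noise, not signal |
| Scoring | running-sum α | 0.25 | canonical weighting of the rank weight |
| Scoring | bins / controls | 24 / 100 | canonical module-score matching |
| DE | p, log2FC | 0.01, 0.25 | the marker thresholds applied to LHS vs LLS |
| Modules | soft power β | 12 | yields an approximately scale-free network on the reference data |
| Modules | metacell k | 25 | de-sparsifies correlations without erasing structure |
| Modules | min size / hubs | 30 / 25 | WGCNA convention / top-kME hub count |
| Selection | Cox p | 0.05 | univariate screen |
| Selection | RF top-k | 20 | importance-ranked short list |

The scoring defaults follow each scorer's original publication — the
defaults of record for these algorithms; all are exposed in
`scoring_params()`.

The QC order is fixed for determinism: the gene filter runs first, and
both cell filters are evaluated on the gene-filtered matrix. The
gene-count bounds are inclusive at both ends; the
mitochondrial rule removes cells strictly above 20%, the universal
convention.

HVG selection uses the classic Seurat-v1 statistic: the variance-to-mean
ratio of normalized (expm1) expression on the log scale, z-scored within
20 equal-frequency bins of the gene mean. An earlier formulation on the
log-transformed values themselves systematically under-ranked
highly-expressed variable genes (the log compresses their
variance-to-mean ratio), which is exactly where planted signatures live;
the expm1-scale statistic does not have that defect. Ties break
lexicographically by gene identifier so the selection is reproducible.

## Numerical choices

- **Wilcoxon tests** (markers, state DE) use the normal approximation
  with tie-corrected variance, switching to exhaustive enumeration of the
  permutation distribution when both groups have ≤ 10 members — the exact
  path is also correct under ties. log2 fold changes follow the Seurat
  convention `log2((mean(expm1 x₁)+1) / (mean(expm1 x₂)+1))`. Raw p
  values drive the filters (the marker-stage convention); BH-adjusted
  values are always reported alongside.
- **PCA** centers and unit-scales genes, treats zero-variance genes as
  inert, and fixes every component's sign so its largest-magnitude
  loading is positive — embeddings are then identical across platforms.
- **Running-sum walk order.** Genes tied on average rank are walked in
  column order (ties.method = "first"), making the integrated sum
  deterministic; the rank *weights* still use the average ranks.
- **Min–max degenerate case.** A constant score vector normalizes to 0.5
  everywhere (with a warning): the method then simply does not
  discriminate, and 0.5 keeps it neutral in the consensus.
- **TOM.** Unsigned adjacency `|r|^β` with zero diagonal;
  `TOM = (A² + A) / (min(kᵢ,kⱼ) + 1 − A)` elementwise, dissimilarity
  `1 − TOM` with zero diagonal. Pearson correlation (not biweight): the
  synthetic data contain no outlier regime that would warrant a robust
  variant, and a switch would be a one-line change.
- **Static tree cut.** Average-linkage clustering of the TOM
  dissimilarity cut at 0.995 of the maximum merge height, with clusters
  under `min_module_size` pooled as grey. The dynamic hybrid cut is a
  large algorithm in its own right; the static cut preserves the
  pipeline's semantics in a fully testable core, and the height is
  configurable.
- **Cox.** Single-covariate partial likelihood with Breslow tie handling,
  Newton–Raphson with step-halving to gradient < 1e-8; Wald p. The test
  suite checks the fit against `survival::coxph` to 1e-6 — the
  implementation never calls it.
- **Boruta decision rule.** Each iteration appends one shuffled shadow
  per real gene; a hit is importance above the *best* shadow. From
  iteration 5 on, a two-sided binomial test of the hit count against 0.5,
  Bonferroni-corrected across the still-undecided genes, confirms or
  rejects at α = 0.01. Importance everywhere is unscaled out-of-bag
  permutation importance, shared with the plain random-forest selector
  for internal consistency.

## Design decisions on genuinely open points

- **ML outcome variable.** The selector set mixes four classification
  methods (LASSO, random forest, Boruta, boosting) with univariate Cox,
  a survival model, on one bulk cohort. The only consistent arrangement:
  Cox runs on (time, event), the other four on the binary label, and the
  cohort table carries both. LASSO is therefore logistic;
  "1000 iterations" is read as repeated cross-validation, implemented as
  `n_repeats` (default 10) with the final penalty the geometric mean of
  the per-repeat λ_min.
- **Candidate pool for selection.** Which genes feed the ML stage is not
  explicit; the pipeline defaults to the up-regulated DEGs that fall in
  co-expression modules (the DEG∩module overlap), capped at the most
  significant 40 so the forest-based selectors run at interactive scale,
  and accepts any user list.
- **Module gene pool.** The co-expression network is built over the top
  HVGs united with the state-associated up-regulated genes, so the
  lactylation program is guaranteed representation; modules fed
  downstream are parameterized rather than hard-coded by color, because
  label sequences are dataset-specific.
- **Quantile convention** — see above; chosen to realize the exact-quarter
  construction.

## What the simulator emulates — and what it does not

`simulate_sc_counts()` draws negative-binomial counts (dispersion 0.5)
around log-normal gene baselines, with discrete cell types (marker-gene
blocks at fold 3), a planted fraction of cells whose signature means are
multiplied by the configured fold, and `MT-` genes tuned to a per-cell
mitochondrial fraction. Signature genes are planted on the upper half of
baseline abundance: curated signatures are built from expressed genes,
and a fold on a near-silent gene is unobservable by construction. The
defaults — 2000 cells, 3000 genes, a 50-gene signature at fold 4 in 25%
of cells — are the package's reference conditions, also used by the demo.

`simulate_modular_expression()` gives exact block correlation via a
per-module latent factor; `simulate_cohort()` plants genes whose effect
acts simultaneously as log-odds on a binary label and log-hazard on
exponential survival times (independent exponential censoring,
approximately calibrated to the configured rate); `simulate_spatial()`
plants a contiguous high-signature block on a spot grid.

Deliberately absent: doublets, ambient RNA, batch effects, cell-cycle
structure, spatially smooth gradients, and any relationship between the
single-cell matrix and the cohort beyond sharing gene names. Passing
tests therefore demonstrate algorithmic correctness and recovery under
clean planted signal — not robustness to the full pathology of real data.

## Problem sizes

The routine test suite runs the pipeline at 600 cells × 800 genes with
correspondingly reduced module and selector settings; the acceptance
checks run the full reference conditions (2000 × 3000 demo, three seeds;
Cox recovery at n = 1000; module recovery on two 50-gene blocks at
within-correlation 0.8). These sizes were chosen as the smallest at which
each planted effect is comfortably identifiable, keeping the whole suite
at interactive latency.

## Known limitations

- The consensus weights all five scorers equally; a principled weighting
  (e.g. by per-method discriminability) is future work.
- The static tree cut can split one planted module across two labels on
  marginal data where the dynamic hybrid cut would not.
- Univariate Cox estimates attenuate when several informative genes act
  simultaneously (omitted-covariate non-collapsibility); selection by p
  value is unaffected, but recovered coefficients are only unbiased for
  a single planted gene.
- The gradient-boosting gain concentrates on informative genes early in
  boosting; with many rounds, later trees spend gain on noise, so the
  mean-gain selection rule, not the gain share, is the stable interface.
- Gene identifiers match exactly and case-sensitively; `match_gene_set()`
  reports the matched fraction so namespace mismatches fail loudly.
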