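# lactoscore

Consensus lactylation-activity scoring and state discovery for single-cell,
spatial and bulk transcriptomics.

Lactylation — the attachment of lactate-derived groups to proteins — varies
strongly across the cells of a tumor, tracking each cell's glycolytic
state. `lactoscore` quantifies that variation from expression data alone:
it scores every cell against a curated lactylation-related gene (LRG)
signature with five independent algorithms, fuses them into a single 0–1
consensus, stratifies cells into **low (LLS)**, **dynamic-transition
(LDTS)** and **high (LHS)** lactylation states by the interquartile-range
rule, and then hunts for the genes that travel with the high-lactylation
program through differential expression, co-expression modules, and a
five-algorithm machine-learning intersection. It is aimed at computational
biologists studying metabolic heterogeneity (the motivating system is
glioblastoma), and every stage is testable on synthetic data with planted
ground truth — no downloads required.

## The score panel

For a cell with genes ranked by descending expression (rank 1 = highest,
average ranks on ties; every rank scorer is therefore invariant under
monotone transforms of a cell's expression):

- **AUC recovery curve** (AUCell-style). With H(x) = number of signature
  genes at rank ≤ x and k = ⌈0.05·N⌉,
  score = Σₓ₌₁..k H(x) / Σₓ₌₁..k min(x, nₛ) ∈ [0, 1].
- **Rank-U** (UCell-style). Ranks capped at r_max (default 1500),
  U = Σ capped ranks − nₛ(nₛ+1)/2, score = 1 − U/(nₛ·r_max).
- **Mean rank** (singscore-style). The mean ascending rank of the
  signature, rescaled by its enumerated extremes to [0, 1].
- **Weighted running sum** (ssGSEA-style). A walk down the ranking that
  rises by (N−rank+1)^α-weighted steps at signature genes and falls by
  1/(N−nₛ) elsewhere; the score integrates the running sum.
- **Bin-matched module score** (AddModuleScore-style). Mean signature
  expression minus the mean of expression-bin-matched control genes.

Each raw score vector is min–max normalized to [0, 1]; the **consensus**
is their per-cell mean (median optional). Cells below the consensus's 25th
percentile are LLS, above the 75th LHS, the rest LDTS.

Downstream: Wilcoxon LHS-vs-LLS differential expression (p < 0.01,
|log2FC| > 0.25), a WGCNA-style co-expression core (metacell aggregation,
soft-power |r|^β adjacency with β = 12, topological overlap, average-link
tree cut, eigengenes, top-25 kME hubs), and feature selection on a
labeled/survival cohort by LASSO, univariate Cox (p < 0.05), random
forest, Boruta shadow features and gradient boosting, intersected into hub
genes.

## Worked example

Simulate 2000 cells with a 50-gene signature over-expressed 4-fold in a
planted 25% of cells, then score, stratify, and test:

```r
library(lactoscore)

sim <- simulate_sc_counts(sim_config(seed = 1))
qc  <- apply_qc(sim$counts)

panel <- lognormalize(qc$counts) |>
  score_all(sim$truth$signature_genes) |>
  classify_states()
glance(panel)
#> # A tibble: 1 × 6
#>   n_cells n_lls n_ldts n_lhs   q25   q75
#>     <int> <int>  <int> <int> <dbl> <dbl>
#> 1    2000   500   1000   500 0.210 0.488

de <- de_states(lognormalize(qc$counts), setNames(panel$state, panel$cell))
head(de, 3)
#> # A tibble: 3 × 5
#>   gene   log2fc         p     p_adj direction
#>   <chr>   <dbl>     <dbl>     <dbl> <chr>
#> 1 G00989   1.96 1.76e-105 5.28e-102 up
#> 2 G01596   2.09 1.19e-103 1.79e-100 up
#> 3 G01417   2.00 2.37e-102 2.37e- 99 up
```

Exactly a quarter of the cells land in each tail state; here all 500
planted cells are recalled as LHS and all 50 signature genes return as
up-regulated DEGs. `autoplot(panel)` draws the consensus distribution by
state, `autoplot(de)` the volcano.

The one-command demo runs the whole pipeline — QC → scoring → states → DE →
metacell co-expression modules → DEG∩module candidates → five-selector
intersection — and writes every intermediate TSV plus a JSON manifest:

```r
res <- run_demo(seed = 1, dir = "demo_run")
res$selection$intersection   # the recovered hub genes
```

A 371-member synthetic stand-in LRG signature ships in GMT format at
`lrg_signature_path()`; real signatures load with `read_gmt()`, and 10x
style sparse matrices with `read_counts_triplet()`.

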