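# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from its definition (loops, enumeration) rather
# than sharing code with the package.

# AUC recovery curve: literal step-function integration over x = 1..k.
oracle_aucell <- function(set_ranks, n, k) {
  num <- 0
  den <- 0
  ns <- length(set_ranks)
  for (x in seq_len(k)) {
    num <- num + sum(set_ranks <= x)
    den <- den + min(x, ns)
  }
  num / den
}

# Rank-U score from the Mann-Whitney definition on capped ranks.
oracle_ucell <- function(set_ranks, r_max) {
  ns <- length(set_ranks)
  capped <- pmin(set_ranks, r_max + 1)
  u <- sum(capped) - ns * (ns + 1) / 2
  min(1, max(0, 1 - u / (ns * r_max)))
}

# Mean-rank score rescaled by its enumerated extremes.
oracle_singscore <- function(set_ranks, n) {
  ns <- length(set_ranks)
  rho <- n - set_ranks + 1
  mr_min <- mean(seq_len(ns))                 # set at the bottom
  mr_max <- mean(seq(n - ns + 1, n))          # set at the top
  (mean(rho) - mr_min) / (mr_max - mr_min)
}

# Weighted running-sum score by literally walking the n steps.
oracle_ssgsea <- function(set_ranks, n, alpha) {
  in_set <- seq_len(n) %in% set_ranks
  w <- (n - set_ranks + 1)^alpha
  w <- w / sum(w)
  rs <- 0
  es <- 0
  ns <- length(set_ranks)
  for (pos in seq_len(n)) {   # pos == rank: all ranks distinct here
    if (in_set[pos]) {
      rs <- rs + w[match(pos, set_ranks)]
    } else {
      rs <- rs - 1 / (n - ns)
    }
    es <- es + rs
  }
  es
}

# Adjusted Rand index from the contingency-table formula.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# A cell expression vector realizing the given descending ranks for the set
# genes at universe size n (all values distinct).
cell_with_set_ranks <- function(set_ranks, n) {
  x <- rev(seq_len(n))  # gene i has descending rank i
  names(x) <- paste0("g", seq_len(n))
  list(expr = x, set = paste0("g", set_ranks))
}

small_counts <- function(values, layer = "counts") {
  count_matrix(
    values,
    cell_ids = paste0("c", seq_len(nrow(values))),
    gene_ids = if (is.null(colnames(values))) paste0("g", seq_len(ncol(values))) else colnames(values),
    layer = layer
  )
}
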