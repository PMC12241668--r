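# Vectorized two-sided Wilcoxon rank-sum tests, one per matrix column.
#
# Normal approximation with the tie-corrected variance; when both groups
# have <= `exact_max` members the p-value comes from exhaustive enumeration
# of all group assignments (permutation distribution of the rank sum), which
# is also correct under ties.

.wilcox_columns <- function(x1, x2, exact_max = 10L) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  stopifnot(n1 > 0, n2 > 0)
  xall <- rbind(x1, x2)
  n <- n1 + n2
  p <- numeric(ncol(xall))
  exact <- n1 <= exact_max && n2 <= exact_max
  if (exact) {
    combos <- utils::combn(n, n1)
  }
  for (j in seq_len(ncol(xall))) {
    r <- rank(xall[, j])
    w_obs <- sum(r[seq_len(n1)])
    if (exact) {
      w_all <- colSums(matrix(r[combos], nrow = n1))
      mu <- n1 * (n + 1) / 2
      p[j] <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-10)
    } else {
      mu <- n1 * (n + 1) / 2
      tie_tab <- table(r)
      tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
      sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
      if (sigma2 <= 0) {
        p[j] <- 1
      } else {
        z <- (w_obs - mu) / sqrt(sigma2)
        p[j] <- 2 * stats::pnorm(-abs(z))
      }
    }
  }
  pmin(p, 1)
}

# Seurat-convention fold change on the log scale:
# log2((mean(expm1(group1)) + 1) / (mean(expm1(group2)) + 1))
.log2_fold_change <- function(x1, x2) {
  m1 <- colMeans(expm1(x1))
  m2 <- colMeans(expm1(x2))
  log2((m1 + 1) / (m2 + 1))
}
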