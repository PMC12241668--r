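test_that("cell gene-count bounds are inclusive and applied after the gene filter", {
  set.seed(1)
  n_genes <- 9000
  detected <- c(150, 500, 8000)
  m <- matrix(0L, 3, n_genes,
              dimnames = list(paste0("c", 1:3), paste0("g", seq_len(n_genes))))
  for (i in 1:3) m[i, seq_len(detected[i])] <- 1L
  cm <- count_matrix(m)
  res <- apply_qc(cm, qc_thresholds(min_cells_per_gene = 1))
  expect_equal(cell_ids(res$counts), "c2")
  expect_equal(res$report$removed[res$report$rule == "cell_min_genes"], 1)
  expect_equal(res$report$removed[res$report$rule == "cell_max_genes"], 1)

  # boundary: exactly 200 and exactly 7000 detected genes are retained
  m2 <- matrix(0L, 2, n_genes)
  m2[1, 1:200] <- 1L
  m2[2, 1:7000] <- 1L
  res2 <- apply_qc(small_counts(m2), qc_thresholds(min_cells_per_gene = 1))
  expect_equal(nrow(res2$counts$values), 2L)
})

test_that("mito fraction exactly at the threshold is retained (strict >)", {
  m <- matrix(0L, 8, 10)
  colnames(m) <- c("MT-1", paste0("g", 1:9))
  m[, ] <- 1L
  m[1, "MT-1"] <- 10L  # fraction 10/19 > 0.2 -> removed
  m[2, "MT-1"] <- 1L   # 1/10 = 0.1 -> kept
  # cell 3: mito exactly 20%: 2 mito among 10 total
  m[3, ] <- 1L
  m[3, "MT-1"] <- 2L
  m[3, "g9"] <- 0L     # total 10, mito 2 -> 0.20 exactly
  cm <- small_counts(m)
  res <- apply_qc(cm, qc_thresholds(min_cells_per_gene = 1,
                                    min_genes_per_cell = 1,
                                    max_genes_per_cell = 100))
  expect_false("c1" %in% cell_ids(res$counts))
  expect_true(all(c("c2", "c3") %in% cell_ids(res$counts)))
})

test_that("lowly detected genes are removed by direct enumeration", {
  set.seed(21)
  m <- matrix(rpois(100 * 50, 3), 100, 50)
  m[m == 0] <- 1L  # every gene detected everywhere...
  rare <- sample(50, 10)
  m[, rare] <- 0L
  for (g in rare) m[sample(100, 4), g] <- 1L  # detected in only 4 cells
  res <- apply_qc(small_counts(m),
                  qc_thresholds(min_genes_per_cell = 1, max_genes_per_cell = 1e5))
  expect_equal(ncol(res$counts$values), 40L)
  expect_equal(res$report$removed[res$report$rule == "gene_min_cells"], 10)
})

test_that("QC is idempotent on simulated data", {
  sim <- simulate_sc_counts(sim_config(n_cells = 300, n_genes = 400, seed = 12))
  once <- apply_qc(sim$counts)
  twice <- apply_qc(once$counts)
  expect_equal(as.matrix(twice$counts$values), as.matrix(once$counts$values))
  expect_true(all(twice$report$removed == 0))
})

test_that("log-normalization has its closed-form properties", {
  m <- rbind(c(0, 0, 0), c(7, 0, 0), c(3, 5, 2))
  ln <- lognormalize(small_counts(m))
  expect_equal(as.numeric(ln$values[1, ]), c(0, 0, 0))
  expect_equal(ln$values[2, 1], log1p(1e4))
  # expm1 row sums return the scale total for nonzero cells
  expect_equal(sum(expm1(ln$values[3, ])), 1e4)
  expect_equal(ln$layer, "lognorm")
})

test_that("HVG selection returns all genes when asked for too many, breaks ties lexicographically", {
  sim <- simulate_sc_counts(sim_config(n_cells = 100, n_genes = 200, seed = 3))
  expect_warning(h <- select_hvgs(sim$counts, 1000), "exceeds")
  expect_setequal(as.vector(h), gene_ids(sim$counts))
  # exact-duplicate genes tie; order must be lexicographic among them
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), z = c(4, 3, 2, 1),
             c = c(1, 2, 3, 4))
  rownames(m) <- paste0("c", 1:4)
  h2 <- select_hvgs(count_matrix(m, layer = "counts"), 4, n_bins = 1)
  tied <- as.vector(h2[h2 %in% c("a", "b", "c")])
  expect_equal(tied, sort(tied))
})

test_that("planted high-fold signature genes are highly variable", {
  sim <- simulate_sc_counts(sim_config(n_cells = 500, n_genes = 1000,
                                       n_celltypes = 1,
                                       lactylation_set_size = 30,
                                       lactylation_fold = 4, seed = 7))
  h <- select_hvgs(sim$counts, 100)  # top decile of 1000 genes
  expect_gte(mean(sim$truth$signature_genes %in% h), 0.9)
})

test_that("PCA matches a reference SVD and fixes component signs", {
  set.seed(5)
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:6)))
  cm <- count_matrix(abs(m), layer = "lognorm")
  emb <- run_pca(cm, n_pcs = 3)
  x <- scale(abs(m))
  sv <- svd(x)
  ref <- sv$u %*% diag(sv$d)
  for (j in 1:3) {
    expect_equal(abs(emb[, j]), abs(ref[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # sign convention: largest-|loading| entry of each component is positive
  rot <- attr(emb, "rotation")
  for (j in seq_len(ncol(rot))) {
    expect_gt(rot[which.max(abs(rot[, j])), j], 0)
  }
  expect_equal(run_pca(cm, n_pcs = 3), emb)

  # rank-1 structure: PC1 dominates
  r1 <- outer(seq_len(20), seq_len(8)) + matrix(rnorm(160, sd = 1e-3), 20)
  cm1 <- count_matrix(abs(r1), cell_ids = paste0("c", 1:20),
                      gene_ids = paste0("g", 1:8), layer = "lognorm")
  e1 <- run_pca(cm1, n_pcs = 3)
  sdev <- attr(e1, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.99)
})

test_that("clustering separates blobs and recovers planted cell types", {
  set.seed(31)
  blob <- rbind(matrix(rnorm(150 * 2), ncol = 2),
                matrix(rnorm(150 * 2, mean = 12), ncol = 2))
  rownames(blob) <- paste0("c", seq_len(nrow(blob)))
  cl <- cluster_cells(blob, resolution = 0.4, k_neighbors = 30)
  expect_equal(sort(unique(cl$cluster)), c(1L, 2L))
  expect_equal(ari(cl$cluster, rep(1:2, each = 150)), 1)

  sim <- simulate_sc_counts(sim_config(n_cells = 400, n_genes = 600,
                                       n_celltypes = 4,
                                       lactylation_fold = 1, seed = 13))
  ln <- lognormalize(apply_qc(sim$counts)$counts)
  emb <- run_pca(ln, select_hvgs(ln, 300), n_pcs = 20)
  cl2 <- cluster_cells(emb)
  truth <- sim$truth$celltype[cl2$cell]
  expect_gte(ari(cl2$cluster, truth), 0.9)
  expect_error(cluster_cells(blob[1:10, ], k_neighbors = 20), "k_neighbors")
})

test_that("marker finding detects a planted marker and nothing under the null", {
  set.seed(41)
  m <- matrix(rpois(200 * 30, 5), 200, 30)
  cm <- small_counts(m)
  groups <- setNames(rep(c("a", "b"), each = 100), cell_ids(cm))
  expect_equal(nrow(find_markers(cm, groups)), 0L)

  m2 <- m
  m2[1:100, 7] <- rpois(100, 40)  # fold 8 in group a
  mk <- find_markers(small_counts(m2), groups)
  expect_true(all(c("a") %in% mk$group))
  expect_true("g7" %in% mk$gene[mk$group == "a"])
  expect_false("g7" %in% mk$gene[mk$group == "b"])  # positive markers only
})

test_that("column Wilcoxon matches the exact test and is monotone-invariant", {
  set.seed(51)
  x1 <- matrix(rnorm(6 * 5), 6, 5)
  x2 <- matrix(rnorm(6 * 5, mean = 1), 6, 5)
  mine <- lactoscore:::.wilcox_columns(x1, x2)
  ref <- vapply(1:5, function(j) {
    wilcox.test(x1[, j], x2[, j], exact = TRUE)$p.value
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-12)

  # large-sample path: invariance under a strictly monotone transform
  y1 <- matrix(rexp(60 * 4), 60, 4)
  y2 <- matrix(rexp(60 * 4, rate = 0.5), 60, 4)
  p_raw <- lactoscore:::.wilcox_columns(y1, y2)
  p_tr <- lactoscore:::.wilcox_columns(log1p(y1)^2, log1p(y2)^2)
  expect_equal(p_raw, p_tr, tolerance = 1e-12)
})
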