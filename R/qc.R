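#' Quality-control thresholds
#'
#' The standard scRNA-seq gate: genes must be detected in at least
#' `min_cells_per_gene` cells; cells must detect between `min_genes_per_cell`
#' and `max_genes_per_cell` genes (inclusive) and carry at most
#' `max_mito_fraction` of their counts on mitochondrial (`mito_prefix`)
#' genes (cells strictly above the fraction are removed).
#'
#' @param min_cells_per_gene Minimum cells a gene must be detected in (default 5).
#' @param min_genes_per_cell Minimum detected genes per cell (default 200).
#' @param max_genes_per_cell Maximum detected genes per cell (default 7000).
#' @param max_mito_fraction Maximum mitochondrial count fraction (default 0.20).
#' @param mito_prefix Gene-name prefix marking mitochondrial genes.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_cells_per_gene = 5L, min_genes_per_cell = 200L,
                          max_genes_per_cell = 7000L,
                          max_mito_fraction = 0.20, mito_prefix = "MT-") {
  stopifnot(min_genes_per_cell <= max_genes_per_cell,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(
    list(min_cells_per_gene = min_cells_per_gene,
         min_genes_per_cell = min_genes_per_cell,
         max_genes_per_cell = max_genes_per_cell,
         max_mito_fraction = max_mito_fraction,
         mito_prefix = mito_prefix),
    class = "qc_thresholds"
  )
}

#' Apply quality-control filters
#'
#' The gene filter runs first; both cell filters are then evaluated on the
#' gene-filtered matrix (detected-gene counts and mitochondrial fractions
#' refer to surviving genes). Gene-count bounds are inclusive; the
#' mitochondrial cut removes cells strictly above the threshold.
#'
#' @param x A [count_matrix()] (counts layer).
#' @param thresholds A [qc_thresholds()].
#' @return List with `counts` (filtered [count_matrix()]) and `report`, a
#'   tibble of per-rule removal counts.
#' @export
apply_qc <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "count_matrix"))
  if (x$layer != "counts") stop("apply_qc expects the counts layer")
  m <- x$values
  gene_cells <- Matrix::colSums(m > 0)
  keep_gene <- gene_cells >= thresholds$min_cells_per_gene
  m2 <- m[, keep_gene, drop = FALSE]

  detected <- Matrix::rowSums(m2 > 0)
  mito <- startsWith(colnames(m2), thresholds$mito_prefix)
  total <- Matrix::rowSums(m2)
  mito_frac <- ifelse(total > 0, Matrix::rowSums(m2[, mito, drop = FALSE]) / total, 0)

  low <- detected < thresholds$min_genes_per_cell
  high <- detected > thresholds$max_genes_per_cell
  mito_out <- mito_frac > thresholds$max_mito_fraction
  keep_cell <- !(low | high | mito_out)

  report <- tibble::tibble(
    rule = c("gene_min_cells", "cell_min_genes", "cell_max_genes",
             "cell_mito_fraction"),
    removed = c(sum(!keep_gene), sum(low), sum(high), sum(mito_out))
  )
  if (!any(keep_cell)) {
    stop(paste0(
      "QC removed every cell; per-rule removals: ",
      paste(sprintf("%s=%d", report$rule, report$removed), collapse = ", ")
    ))
  }
  out <- count_matrix(m2[keep_cell, , drop = FALSE], layer = x$layer)
  list(counts = out, report = report)
}

#' Log-normalize counts
#'
#' Per cell, counts are scaled to `scale_total` total counts and
#' `log(1 + x)` transformed (natural log). Cells with zero total counts stay
#' all-zero.
#'
#' @param x A [count_matrix()] (counts layer).
#' @param scale_total Per-cell target total (default 1e4).
#' @return A [count_matrix()] with layer `"lognorm"`.
#' @export
lognormalize <- function(x, scale_total = 1e4) {
  stopifnot(inherits(x, "count_matrix"))
  if (x$layer == "lognorm") return(x)
  m <- x$values
  totals <- Matrix::rowSums(m)
  fac <- ifelse(totals > 0, scale_total / totals, 0)
  m <- Matrix::Diagonal(x = fac) %*% m
  m <- methods::as(m, "CsparseMatrix")
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(x$values)
  count_matrix(m, layer = "lognorm")
}

.ensure_lognorm <- function(x, scale_total = 1e4) {
  if (x$layer == "lognorm") x else lognormalize(x, scale_total)
}

#' Select highly variable genes
#'
#' Classic binned standardized dispersion: per gene, the
#' variance-to-mean ratio of the normalized (expm1 of log-normalized)
#' values on the log scale, z-scored within `n_bins` equal-frequency bins
#' of the gene mean so that expression level does not confound
#' variability. Ties break lexicographically by gene identifier; genes
#' never detected rank last.
#'
#' @param x A [count_matrix()] (either layer; counts are log-normalized
#'   first).
#' @param n_hvgs Number of genes to return (default 2000). If larger than
#'   the gene count, all genes are returned with a warning.
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of selected gene ids, ordered by decreasing
#'   standardized dispersion, with a tibble of per-gene statistics in
#'   attribute `"stats"`.
#' @export
select_hvgs <- function(x, n_hvgs = 2000, n_bins = 20) {
  stopifnot(inherits(x, "count_matrix"))
  ln <- .ensure_lognorm(x)
  m <- ln$values
  m@x <- expm1(m@x)
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  v <- (Matrix::colSums(m^2) - n * mu^2) / max(1, n - 1)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), NA_real_)
  stats_tbl <- tibble::tibble(gene = colnames(m), mean = mu, dispersion = disp) |>
    dplyr::mutate(bin = dplyr::ntile(.data$mean, n_bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(
      dispersion_z = {
        s <- stats::sd(.data$dispersion, na.rm = TRUE)
        if (is.na(s) || s == 0) {
          ifelse(is.na(.data$dispersion), -Inf, 0)
        } else {
          z <- (.data$dispersion - mean(.data$dispersion, na.rm = TRUE)) / s
          ifelse(is.na(z), -Inf, z)
        }
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$dispersion_z), .data$gene)
  if (n_hvgs > ncol(m)) {
    warning(sprintf("n_hvgs (%d) exceeds gene count (%d); returning all genes",
                    n_hvgs, ncol(m)))
    n_hvgs <- ncol(m)
  }
  out <- stats_tbl$gene[seq_len(n_hvgs)]
  attr(out, "stats") <- stats_tbl
  out
}

#' Principal-component embedding
#'
#' Genes are centered and unit-scaled (zero-variance genes contribute
#' nothing) before the decomposition. Component signs are fixed so that each
#' loading vector's largest-magnitude entry is positive, making the
#' embedding reproducible across platforms.
#'
#' @param x A [count_matrix()] (log-normalized; counts are normalized first).
#' @param genes Optional gene subset (e.g. from [select_hvgs()]).
#' @param n_pcs Number of components (default 20).
#' @return A cells x `n_pcs` numeric matrix with attributes `"sdev"` and
#'   `"rotation"`.
#' @export
run_pca <- function(x, genes = NULL, n_pcs = 20) {
  stopifnot(inherits(x, "count_matrix"))
  ln <- .ensure_lognorm(x)
  m <- as.matrix(ln$values)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(m))
    if (length(missing)) stop(sprintf("unknown genes in subset: %s", missing[1]))
    m <- m[, genes, drop = FALSE]
  }
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0] <- 1
  m <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  n_pcs <- min(n_pcs, ncol(m), nrow(m) - 1)
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE, rank. = n_pcs)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(m)
  attr(scores, "sdev") <- pc$sdev
  attr(scores, "rotation") <- rot
  scores
}

#' Cluster cells on an embedding
#'
#' Shared-nearest-neighbor graph (Jaccard-weighted k-nearest-neighbor
#' overlap, pruned below 1/15) followed by Louvain community detection —
#' the standard Seurat-style recipe, with the graph community step delegated
#' to igraph. Cluster labels are consecutive integers ordered by descending
#' cluster size.
#'
#' @param embedding Cells x dims matrix (e.g. from [run_pca()]).
#' @param resolution Louvain resolution (default 0.8).
#' @param k_neighbors Neighborhood size for the SNN graph (default 20).
#' @return Tibble with columns `cell` and `cluster` (integer).
#' @export
cluster_cells <- function(embedding, resolution = 0.8, k_neighbors = 20) {
  n <- nrow(embedding)
  if (n <= k_neighbors) {
    stop(sprintf("need more cells (%d) than k_neighbors (%d)", n, k_neighbors))
  }
  d <- as.matrix(stats::dist(embedding))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  a <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_neighbors),
    j = as.vector(t(nn)), x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(a)
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  tibble::tibble(
    cell = rownames(embedding),
    cluster = as.integer(relabel[as.character(memb)])
  )
}

.as_group_vector <- function(groups) {
  if (is.data.frame(groups)) {
    stats::setNames(groups[[2]], groups[[1]])
  } else if (!is.null(names(groups))) {
    groups
  } else {
    stop("groups must be a named vector or a two-column data frame")
  }
}

#' Per-cluster positive marker genes
#'
#' For each group, every gene is tested group-vs-rest with a two-sided
#' Wilcoxon rank-sum test on log-normalized values; the reported table keeps
#' positive markers with `p < p_max` and `log2fc > lfc_min`.
#'
#' @param x A [count_matrix()].
#' @param groups Named group vector (cell -> group) or a two-column data
#'   frame such as [cluster_cells()] output.
#' @param p_max Raw p-value cut (default 0.01).
#' @param lfc_min log2 fold-change cut (default 0.25).
#' @return Tibble: `group`, `gene`, `log2fc`, `p`, `p_adj` (BH within
#'   group), sorted by group then p.
#' @export
find_markers <- function(x, groups, p_max = 0.01, lfc_min = 0.25) {
  stopifnot(inherits(x, "count_matrix"))
  ln <- .ensure_lognorm(x)
  groups <- .as_group_vector(groups)
  m <- as.matrix(ln$values)
  groups <- groups[rownames(m)]
  if (anyNA(groups)) stop("groups must cover every cell in the matrix")
  out <- purrr::map(sort(unique(groups)), function(grp) {
    in_grp <- groups == grp
    if (all(in_grp) || !any(in_grp)) {
      return(NULL)
    }
    p <- .wilcox_columns(m[in_grp, , drop = FALSE], m[!in_grp, , drop = FALSE])
    lfc <- .log2_fold_change(m[in_grp, , drop = FALSE], m[!in_grp, , drop = FALSE])
    tibble::tibble(
      group = grp, gene = colnames(m), log2fc = lfc, p = p,
      p_adj = stats::p.adjust(p, "BH")
    ) |>
      dplyr::filter(.data$p < p_max, .data$log2fc > lfc_min) |>
      dplyr::arrange(.data$p)
  })
  dplyr::bind_rows(out)
}
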