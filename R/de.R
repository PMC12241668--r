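#' Differential expression between high and low lactylation states
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of LHS versus LLS cells on
#' log-normalized expression (normal approximation with tie correction;
#' exhaustive enumeration when both groups have at most 10 cells), with the
#' Seurat-convention log2 fold change. BH adjustment runs over all tested
#' genes; the filter keeps both directions.
#'
#' @param x A [count_matrix()].
#' @param states State vector aligned with the cells (the `state` column of
#'   [classify_states()] output, or a named vector / two-column data frame).
#' @param p_max Raw p-value cut (default 0.01).
#' @param lfc_min Absolute log2 fold-change cut (default 0.25).
#' @param filter Return only passing genes (default) or the full table.
#' @return A `de_result` tibble: `gene`, `log2fc` (LHS over LLS), `p`,
#'   `p_adj`, `direction` (`up` = higher in LHS).
#' @export
de_states <- function(x, states, p_max = 0.01, lfc_min = 0.25, filter = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  ln <- .ensure_lognorm(x)
  m <- as.matrix(ln$values)
  if (is.data.frame(states) || !is.null(names(states))) {
    states <- .as_group_vector(states)[rownames(m)]
  } else {
    stopifnot(length(states) == nrow(m))
  }
  hi <- which(states == "LHS")
  lo <- which(states == "LLS")
  if (length(hi) == 0) stop("state 'LHS' is empty")
  if (length(lo) == 0) stop("state 'LLS' is empty")
  p <- .wilcox_columns(m[hi, , drop = FALSE], m[lo, , drop = FALSE])
  lfc <- .log2_fold_change(m[hi, , drop = FALSE], m[lo, , drop = FALSE])
  out <- tibble::tibble(
    gene = colnames(m), log2fc = lfc, p = p,
    p_adj = stats::p.adjust(p, "BH"),
    direction = ifelse(lfc >= 0, "up", "down")
  )
  if (filter) {
    out <- dplyr::filter(out, .data$p < p_max, abs(.data$log2fc) > lfc_min)
  }
  out <- dplyr::arrange(out, .data$p)
  tibble::new_tibble(out, class = "de_result")
}

#' Order-stable intersection of two gene lists
#'
#' Exact string matching; the result keeps the order of the first list.
#'
#' @param a,b Character vectors.
#' @return Character vector of shared genes in `a`'s order.
#' @export
intersect_genes <- function(a, b) {
  a[a %in% b]
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of seeing at
#' least the observed overlap between the query and the set, given the
#' background universe; BH adjustment across sets. Query and sets are
#' restricted to the background first.
#'
#' @param query Character vector of query genes (non-empty).
#' @param collection Gene-set tibble from [read_gmt()].
#' @param background Character vector: the gene universe (e.g. all genes
#'   surviving QC).
#' @return Tibble: `set_name`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p`, `p_adj`, sorted by p.
#' @export
ora_hypergeometric <- function(query, collection, background) {
  if (length(query) == 0) stop("empty query gene list")
  background <- unique(background)
  q <- unique(intersect_genes(query, background))
  n_bg <- length(background)
  res <- purrr::pmap(
    collection[c("set_name", "genes")],
    function(set_name, genes) {
      s <- unique(intersect_genes(genes, background))
      k <- length(intersect_genes(q, s))
      p <- stats::phyper(k - 1, length(s), n_bg - length(s), length(q),
                         lower.tail = FALSE)
      tibble::tibble(
        set_name = set_name, overlap = k, set_size = length(s),
        query_size = length(q), background_size = n_bg, p = p
      )
    }
  )
  out <- dplyr::bind_rows(res)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  dplyr::arrange(out, .data$p)
}
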