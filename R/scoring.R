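#' Scoring parameters for the five activity scorers
#'
#' Defaults follow each scorer's canonical publication: the recovery-curve
#' scorer integrates over the top 5% of ranks, the rank-U scorer caps ranks
#' at 1500, the weighted running-sum exponent is 0.25, and the module score
#' uses 24 expression bins with 100 control genes per signature gene.
#'
#' @param auc_max_rank_fraction Fraction of top ranks integrated by the AUC
#'   recovery-curve scorer (k = ceiling(fraction * n_genes)).
#' @param ucell_max_rank Rank ceiling for the rank-U scorer.
#' @param ssgsea_alpha Rank-weight exponent for the running-sum scorer.
#' @param module_n_bins Expression bins for control-gene matching.
#' @param module_n_controls Control genes drawn per signature gene.
#' @param seed Seed for the control-gene draw.
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(auc_max_rank_fraction = 0.05, ucell_max_rank = 1500,
                           ssgsea_alpha = 0.25, module_n_bins = 24,
                           module_n_controls = 100, seed = 0L) {
  stopifnot(auc_max_rank_fraction > 0, auc_max_rank_fraction <= 1,
            ucell_max_rank >= 1, ssgsea_alpha >= 0)
  structure(
    list(auc_max_rank_fraction = auc_max_rank_fraction,
         ucell_max_rank = ucell_max_rank, ssgsea_alpha = ssgsea_alpha,
         module_n_bins = module_n_bins, module_n_controls = module_n_controls,
         seed = as.integer(seed)),
    class = "scoring_params"
  )
}

#' Per-cell gene ranks by descending expression
#'
#' Rank 1 is the most expressed gene of the cell; ties get the average rank,
#' so every scorer built on these ranks is deterministic and invariant under
#' strictly monotone transformations of a cell's expression vector.
#'
#' @param x A [count_matrix()] or a plain cells x genes matrix.
#' @return Dense cells x genes matrix of ranks.
#' @export
rank_matrix <- function(x) {
  m <- if (inherits(x, "count_matrix")) as.matrix(x$values) else as.matrix(x)
  r <- t(apply(m, 1, function(row) rank(-row)))
  dimnames(r) <- dimnames(m)
  r
}

.as_rank_matrix <- function(ranks) {
  if (is.null(dim(ranks))) matrix(ranks, nrow = 1, dimnames = list(NULL, names(ranks)))
  else as.matrix(ranks)
}

.set_columns <- function(ranks, genes) {
  if (is.character(genes)) {
    idx <- match(genes, colnames(ranks))
    if (anyNA(idx)) stop(sprintf("gene '%s' not present in rank matrix", genes[which(is.na(idx))[1]]))
    idx
  } else {
    as.integer(genes)
  }
}

#' AUC recovery-curve score (AUCell-style)
#'
#' The recovery curve counts how many signature genes appear within the top
#' x ranks of the cell; the score is the area under that step function over
#' x = 1..k, normalized by the maximal achievable area, so 1 means the
#' signature occupies the very top of the cell's ranking.
#'
#' @param ranks Rank vector (one cell) or cells x genes rank matrix from
#'   [rank_matrix()].
#' @param genes Signature genes (names or column indices).
#' @param max_rank_fraction Top-rank fraction integrated
#'   (k = ceiling(fraction * n_genes)).
#' @return Numeric score(s) in \[0, 1\].
#' @export
score_aucell <- function(ranks, genes, max_rank_fraction = 0.05) {
  r <- .as_rank_matrix(ranks)
  idx <- .set_columns(r, genes)
  n <- ncol(r)
  ns <- length(idx)
  k <- ceiling(max_rank_fraction * n)
  contrib <- pmax(k - ceiling(r[, idx, drop = FALSE]) + 1, 0)
  denom <- sum(pmin(seq_len(k), ns))
  unname(rowSums(contrib) / denom)
}

#' Rank-U score (UCell-style)
#'
#' Mann-Whitney-U-based signature score: ranks beyond `max_rank` are capped
#' at `max_rank + 1`, the U statistic of the capped signature ranks is
#' normalized to \[0, 1\], and 1 means the signature holds the top ranks.
#'
#' @inheritParams score_aucell
#' @param max_rank Rank ceiling (must be at least the signature size).
#' @return Numeric score(s) in \[0, 1\].
#' @export
score_ucell <- function(ranks, genes, max_rank = 1500) {
  r <- .as_rank_matrix(ranks)
  idx <- .set_columns(r, genes)
  ns <- length(idx)
  if (max_rank < ns) stop("max_rank must be >= signature size")
  capped <- pmin(r[, idx, drop = FALSE], max_rank + 1)
  u <- rowSums(capped) - ns * (ns + 1) / 2
  unname(pmin(1, pmax(0, 1 - u / (ns * max_rank))))
}

#' Mean-rank score (singscore-style)
#'
#' The mean ascending rank of the signature genes, rescaled by its
#' theoretical minimum and maximum so the score lies in \[0, 1\]: 0 when the
#' signature sits at the bottom of the cell's ranking, 1 at the top.
#'
#' @inheritParams score_aucell
#' @return Numeric score(s) in \[0, 1\].
#' @export
score_singscore <- function(ranks, genes) {
  r <- .as_rank_matrix(ranks)
  idx <- .set_columns(r, genes)
  n <- ncol(r)
  ns <- length(idx)
  rho <- n - r[, idx, drop = FALSE] + 1
  mr <- rowMeans(rho)
  unname((mr - (ns + 1) / 2) / (n - ns))
}

#' Weighted running-sum enrichment score (ssGSEA-style)
#'
#' Walks the cell's genes from highest to lowest expression, incrementing a
#' running sum at signature genes (weight proportional to the rank weight
#' `(n - rank + 1)^alpha`) and decrementing by `1/(n - n_set)` elsewhere;
#' the score is the integrated running sum over all steps. Unbounded; the
#' consensus stage min-max normalizes it.
#'
#' @inheritParams score_aucell
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Numeric score(s), unbounded.
#' @export
score_ssgsea <- function(ranks, genes, alpha = 0.25) {
  r <- .as_rank_matrix(ranks)
  idx <- .set_columns(r, genes)
  n <- ncol(r)
  ns <- length(idx)
  if (ns >= n) stop("signature must be smaller than the gene universe")
  # step positions: ties in the average ranks are walked in column order
  pos <- t(apply(r, 1, function(row) rank(row, ties.method = "first")))
  w <- (n - r[, idx, drop = FALSE] + 1)^alpha
  w <- w / rowSums(w)
  steps_left_set <- n - pos[, idx, drop = FALSE] + 1
  inc <- rowSums(steps_left_set * w)
  dec <- (n * (n + 1) / 2 - rowSums(steps_left_set)) / (n - ns)
  unname(inc - dec)
}

#' Bin-matched module score (AddModuleScore-style)
#'
#' Genes are binned by average log-normalized expression; each signature
#' gene contributes `n_controls` control genes drawn from its bin, and the
#' score is the per-cell mean signature expression minus the mean control
#' expression. The control draw is seeded, so scores are reproducible.
#'
#' @param x A [count_matrix()] (counts are log-normalized first).
#' @param genes Signature gene names.
#' @param n_bins Number of equal-frequency expression bins (default 24).
#' @param n_controls Controls drawn per signature gene; drawn without
#'   replacement within the bin, with replacement when the bin is smaller.
#' @param seed Seed for the control draw.
#' @return Named numeric vector of per-cell scores (unbounded).
#' @export
score_modulescore <- function(x, genes, n_bins = 24, n_controls = 100,
                              seed = 0L) {
  stopifnot(inherits(x, "count_matrix"))
  ln <- .ensure_lognorm(x)
  m <- as.matrix(ln$values)
  idx <- .set_columns(m, genes)
  avg <- colMeans(m)
  bin <- dplyr::ntile(avg, min(n_bins, ncol(m)))
  set.seed(seed)
  controls <- unlist(lapply(idx, function(i) {
    pool <- which(bin == bin[i])
    if (length(pool) >= n_controls) {
      sample(pool, n_controls)
    } else {
      sample(pool, n_controls, replace = TRUE)
    }
  }))
  score <- rowMeans(m[, idx, drop = FALSE]) - rowMeans(m[, controls, drop = FALSE])
  stats::setNames(score, rownames(m))
}

#' Score every cell with the five activity scorers
#'
#' Runs the AUC recovery-curve, rank-U, mean-rank, weighted running-sum and
#' bin-matched module scorers against one signature and returns the raw
#' per-cell score panel. Signature members absent from the matrix are
#' dropped (with a prominent warning when fewer than half match).
#'
#' @param x A [count_matrix()].
#' @param genes Character vector of signature genes (or a one-row tibble
#'   from [read_gmt()], whose first set is used).
#' @param params A [scoring_params()].
#' @return Tibble with columns `cell`, `aucell`, `ucell`, `singscore`,
#'   `ssgsea`, `module_score` (raw scores; all `NA` if no gene matches).
#' @export
score_all <- function(x, genes, params = scoring_params()) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.data.frame(genes)) genes <- genes$genes[[1]]
  ln <- .ensure_lognorm(x)
  matched <- match_gene_set(genes, gene_ids(ln))
  if (length(matched) == 0) {
    warning("no signature gene matched the matrix; scores are missing")
    return(tibble::tibble(
      cell = cell_ids(ln), aucell = NA_real_, ucell = NA_real_,
      singscore = NA_real_, ssgsea = NA_real_, module_score = NA_real_
    ))
  }
  r <- rank_matrix(ln)
  tibble::tibble(
    cell = cell_ids(ln),
    aucell = score_aucell(r, matched, params$auc_max_rank_fraction),
    ucell = score_ucell(r, matched, max(params$ucell_max_rank, length(matched))),
    singscore = score_singscore(r, matched),
    ssgsea = score_ssgsea(r, matched, params$ssgsea_alpha),
    module_score = as.numeric(score_modulescore(
      ln, matched, params$module_n_bins, params$module_n_controls, params$seed
    ))
  )
}
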