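#' Min-max normalize a score vector to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant vector maps to 0.5 everywhere (with
#' a warning) and missing values propagate.
#'
#' @param x Numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  lo <- min(x[ok]); hi <- max(x[ok])
  if (hi == lo) {
    warning("constant score vector: min-max normalization set to 0.5")
    return(ifelse(ok, 0.5, NA_real_))
  }
  (x - lo) / (hi - lo)
}

.score_methods <- c("aucell", "ucell", "singscore", "ssgsea", "module_score")

#' Fuse normalized scores into a consensus
#'
#' Per cell, the unweighted mean (or median) of the available normalized
#' method scores; cells missing every method get a missing consensus.
#'
#' @param norm A data frame / matrix of normalized per-method scores.
#' @param fusion `"mean"` (default) or `"median"`.
#' @return Numeric consensus vector.
#' @export
consensus_scores <- function(norm, fusion = c("mean", "median")) {
  fusion <- match.arg(fusion)
  m <- as.matrix(norm)
  f <- if (fusion == "mean") rowMeans else function(x, na.rm) apply(x, 1, stats::median, na.rm = na.rm)
  out <- suppressWarnings(f(m, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  if (anyNA(out)) {
    warning(sprintf("%d cell(s) have no available method score", sum(is.na(out))))
  }
  out
}

#' Assign lactylation states by the interquartile-range rule
#'
#' Cells below the 25th percentile of the consensus score are the low
#' lactylation state (LLS), cells above the 75th percentile the high state
#' (LHS), and everything in between — boundary ties included — the dynamic
#' transition state (LDTS). Quantiles use R's default order-statistic
#' interpolation (type 7) with strict inequalities, so with all-distinct
#' scores the LLS and LHS groups each hold a quarter of the cells.
#'
#' @param x Numeric consensus vector (at least 8 non-missing values).
#' @return Factor with levels `LLS`, `LDTS`, `LHS` (missing input gives
#'   missing state) and attribute `"iqr_bounds"` (tibble `q25`, `q75`).
#' @export
assign_states <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 8) stop("need at least 8 non-missing consensus scores for quartiles")
  q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2] && stats::var(x[ok]) == 0) {
    warning("all consensus scores are tied: every cell assigned LDTS")
  }
  state <- rep(NA_character_, length(x))
  state[ok] <- "LDTS"
  state[ok & x < q[1]] <- "LLS"
  state[ok & x > q[2]] <- "LHS"
  out <- factor(state, levels = c("LLS", "LDTS", "LHS"))
  attr(out, "iqr_bounds") <- tibble::tibble(q25 = q[1], q75 = q[2])
  out
}

#' Normalize, fuse and stratify a raw score panel
#'
#' Takes the raw per-cell panel from [score_all()], min-max normalizes each
#' method to \[0, 1\], fuses the normalized scores into the consensus, and
#' assigns the LLS / LDTS / LHS state by the interquartile-range rule.
#'
#' @param panel Tibble from [score_all()] (column `cell` plus one raw score
#'   column per method).
#' @param fusion `"mean"` (default) or `"median"`.
#' @return A `score_panel` tibble: `cell`, raw scores, `<method>_norm`
#'   columns, `consensus`, `state`; quartile bounds in attribute
#'   `"iqr_bounds"`.
#' @export
classify_states <- function(panel, fusion = c("mean", "median")) {
  fusion <- match.arg(fusion)
  methods <- intersect(.score_methods, names(panel))
  if (length(methods) == 0) stop("panel contains no recognized score columns")
  norm <- purrr::map_dfc(panel[methods], minmax_normalize)
  names(norm) <- paste0(methods, "_norm")
  cons <- consensus_scores(norm, fusion)
  state <- assign_states(cons)
  out <- dplyr::bind_cols(panel, norm)
  out$consensus <- cons
  out$state <- as.vector(state)
  out <- tibble::new_tibble(out, class = "score_panel")
  attr(out, "iqr_bounds") <- attr(state, "iqr_bounds")
  out
}

#' Score and stratify spatial spots
#'
#' Spots are treated exactly like cells: scored with the five algorithms,
#' min-max normalized, fused, and assigned LLS / LDTS / LHS; the result is
#' joined back to the spot coordinates for mapping.
#'
#' @param x A spots x genes [count_matrix()].
#' @param coords Tibble with columns `spot`, `x`, `y`.
#' @param genes Signature genes.
#' @param params A [scoring_params()].
#' @param fusion Consensus fusion rule.
#' @return A `score_panel` tibble with `x`/`y` coordinate columns appended.
#' @export
score_spatial <- function(x, coords, genes, params = scoring_params(),
                          fusion = "mean") {
  panel <- score_all(x, genes, params)
  panel <- classify_states(panel, fusion)
  out <- dplyr::left_join(panel, coords, by = c(cell = "spot"))
  attr(out, "iqr_bounds") <- attr(panel, "iqr_bounds")
  tibble::new_tibble(out, class = "score_panel")
}
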