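#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection report
#'
#' One row per (algorithm, gene) pair, with a flag for membership in the
#' five-way intersection.
#'
#' @param x A `selection_report` from [select_features()].
#' @param ... Unused.
#' @return Tibble: `algorithm`, `gene`, `in_intersection`.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  purrr::imap_dfr(x$selections, function(genes, alg) {
    if (length(genes) == 0) return(tibble::tibble())
    tibble::tibble(algorithm = alg, gene = genes,
                   in_intersection = genes %in% x$intersection)
  })
}

#' Summarize a selection report
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return One-row tibble with per-algorithm selection counts and the
#'   intersection size.
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  counts <- purrr::map_int(x$selections, length)
  out <- tibble::as_tibble(as.list(stats::setNames(
    as.integer(counts), paste0("n_", names(counts))
  )))
  out$n_intersection <- length(x$intersection)
  out
}

#' Tidy a co-expression module fit
#'
#' One row per gene with its module, own-module kME and hub status
#' (grey genes have missing kME and are never hubs).
#'
#' @param x A `coexpression_modules` from [eigengene_kme()] or
#'   [find_coexpression_modules()].
#' @param ... Unused.
#' @return Tibble: `gene`, `module`, `kme`, `is_hub`.
#' @method tidy coexpression_modules
#' @export
tidy.coexpression_modules <- function(x, ...) {
  genes <- names(x$modules)
  kme_own <- vapply(seq_along(genes), function(i) {
    mod <- x$modules[i]
    if (mod == "grey") NA_real_ else x$kme[genes[i], mod]
  }, numeric(1))
  hubs <- unlist(x$hubs, use.names = FALSE)
  tibble::tibble(
    gene = genes, module = unname(x$modules), kme = kme_own,
    is_hub = genes %in% hubs
  )
}

#' Summarize a co-expression module fit
#'
#' @param x A `coexpression_modules`.
#' @param ... Unused.
#' @return Tibble with one row per module: size, hub count, mean own-module
#'   kME.
#' @method glance coexpression_modules
#' @export
glance.coexpression_modules <- function(x, ...) {
  td <- tidy(x)
  td |>
    dplyr::filter(.data$module != "grey") |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_hubs = sum(.data$is_hub),
      mean_kme = mean(.data$kme),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_genes))
}

#' Summarize a score panel
#'
#' @param x A `score_panel` tibble from [classify_states()].
#' @param ... Unused.
#' @return One-row tibble: cell count, state counts, quartile bounds.
#' @method glance score_panel
#' @export
glance.score_panel <- function(x, ...) {
  b <- attr(x, "iqr_bounds")
  tibble::tibble(
    n_cells = nrow(x),
    n_lls = sum(x$state == "LLS", na.rm = TRUE),
    n_ldts = sum(x$state == "LDTS", na.rm = TRUE),
    n_lhs = sum(x$state == "LHS", na.rm = TRUE),
    q25 = b$q25, q75 = b$q75
  )
}
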