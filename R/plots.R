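#' Plot a score panel
#'
#' Violin/jitter view of the consensus score by lactylation state, with the
#' quartile boundaries drawn as dashed lines.
#'
#' @param object A `score_panel` from [classify_states()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot score_panel
#' @export
autoplot.score_panel <- function(object, ...) {
  b <- attr(object, "iqr_bounds")
  df <- dplyr::filter(object, !is.na(.data$state))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$consensus,
                                   fill = .data$state)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(b$q25, b$q75), linetype = "dashed") +
    ggplot2::labs(x = "lactylation state", y = "consensus score") +
    ggplot2::theme_minimal()
}

#' Map lactylation states over spatial spot coordinates
#'
#' @param panel A spatial `score_panel` from [score_spatial()].
#' @param fill `"state"` (default) or `"consensus"`.
#' @return A ggplot object.
#' @export
plot_spatial_states <- function(panel, fill = c("state", "consensus")) {
  fill <- match.arg(fill)
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = fill) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [de_states()] (run with
#'   `filter = FALSE` for the full background cloud).
#' @param p_max,lfc_min Thresholds drawn and used for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, p_max = 0.01, lfc_min = 0.25, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    status = dplyr::case_when(
      .data$p < p_max & .data$log2fc > lfc_min ~ "up in LHS",
      .data$p < p_max & .data$log2fc < -lfc_min ~ "down in LHS",
      TRUE ~ "ns"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   color = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dotted") +
    ggplot2::scale_color_manual(values = c(
      "up in LHS" = "firebrick", "down in LHS" = "steelblue", "ns" = "grey70"
    )) +
    ggplot2::labs(x = "log2 fold change (LHS / LLS)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Scale-free fit curve for soft-power selection
#'
#' @param fit The `fit` tibble from [pick_soft_power()].
#' @param rsq_cut Threshold line (default 0.8).
#' @return A ggplot object.
#' @export
plot_soft_power <- function(fit, rsq_cut = 0.8) {
  ggplot2::ggplot(fit, ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = rsq_cut, linetype = "dashed") +
    ggplot2::labs(x = "soft-threshold power", y = "signed scale-free R²") +
    ggplot2::theme_minimal()
}

#' Per-algorithm selection counts and the intersection
#'
#' @param object A `selection_report` from [select_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  df <- glance(object) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "set",
                        values_to = "n_genes") |>
    dplyr::mutate(set = sub("^n_", "", .data$set))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$set, -.data$n_genes),
                                   y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "selected genes") +
    ggplot2::theme_minimal()
}
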