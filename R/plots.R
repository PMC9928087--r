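# ggplot2 views of the main result types.

#' Scatter plot of mRNA versus protein log2 fold changes
#'
#' The comparative view that makes post-transcriptional control visible:
#' genes far from the diagonal on the protein axis but near zero on the
#' mRNA axis are candidates for translational regulation.
#'
#' @param classes Tibble from [classify_fold_changes()].
#' @param fc_threshold Threshold lines to draw (default 1).
#' @return A ggplot object.
#' @export
plot_expression_comparison <- function(classes, fc_threshold = 1) {
  ggplot2::ggplot(classes,
                  ggplot2::aes(.data$mrna_log2fc, .data$protein_log2fc,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = "mRNA log2 fold change",
      y = "protein log2 fold change",
      colour = NULL,
      title = "mRNA vs protein abundance changes"
    ) +
    ggplot2::theme_minimal()
}

#' Carriage proportions per taxon family
#'
#' @param tab Tibble from [taxon_contingency()].
#' @return A ggplot object (stacked proportions of carriers per family).
#' @export
plot_carriage <- function(tab) {
  long <- tidyr::pivot_longer(tab, c("carriers", "non_carriers"),
                              names_to = "carriage", values_to = "n")
  ggplot2::ggplot(long,
                  ggplot2::aes(stats::reorder(.data$family, -.data$n),
                               .data$n, fill = .data$carriage)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of plasmids", fill = NULL,
                  title = "Regulator carriage by plasmid family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Percent Rmax per oligo and protein variant
#'
#' Bars of mean percent Rmax with the conventional 50% (weak/strong call)
#' and 100% (1:1 stoichiometry) reference lines.
#'
#' @param spr Tibble from [spr_percent_rmax()] with `oligo_id`, `pct_rmax`
#'   and optionally `variant`.
#' @return A ggplot object.
#' @export
plot_percent_rmax <- function(spr) {
  has_variant <- "variant" %in% names(spr)
  grp <- c("oligo_id", if (has_variant) "variant")
  means <- spr %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(pct = mean(.data$pct_rmax),
                     sd = stats::sd(.data$pct_rmax), .groups = "drop")
  p <- ggplot2::ggplot(means, ggplot2::aes(.data$oligo_id, .data$pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "solid",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted",
                        colour = "grey40")
  p <- if (has_variant) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$variant),
                          position = ggplot2::position_dodge())
  } else {
    p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(x = NULL, y = "% Rmax",
                  title = "SPR response relative to theoretical maximum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
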