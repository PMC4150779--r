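#' Plot TSS-centered peak occupancy curves
#'
#' Percent of genes with at least one peak within a window of each size
#' centered on the TSS, one line per gene set (baseline included).
#'
#' @param window_percent The `window_percent` tibble from
#'   [occupancy_profiles()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(window_percent) {
  ggplot2::ggplot(window_percent,
                  ggplot2::aes(x = .data$window_bp, y = .data$percent,
                               colour = .data$gene_set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "window centered on TSS (bp)",
                  y = "% genes with ≥ 1 peak", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the deacetylation peak-offset histogram
#'
#' @param histogram Output of [tss_offset_histogram()].
#' @return A ggplot object.
#' @export
plot_tss_offsets <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$n)) +
    ggplot2::geom_col(width = histogram$bin_end[1] - histogram$bin_start[1]) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "deacetylation peak offset from TSS (bp)",
                  y = "promoters") +
    ggplot2::theme_minimal()
}

#' RPKM dot plot of the two conditions
#'
#' Untreated vs LPS1h RPKM on log scales, coloured by the tier label.
#'
#' @param expression A classified expression tibble ([classify_change()]).
#' @param tier Which tier label to colour by.
#' @param floor Plotting floor for zero RPKM values.
#' @return A ggplot object.
#' @export
plot_expression <- function(expression, tier = 2, floor = 0.05) {
  lab <- paste0("label_", tier)
  df <- mutate(expression,
               x = pmax(.data$rpkm_untreated, floor),
               y = pmax(.data$rpkm_LPS1h, floor),
               label = .data[[lab]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      induced = "forestgreen", silenced = "firebrick",
      unchanged = "grey30", not_expressed = "grey80")) +
    ggplot2::labs(x = "RPKM, untreated", y = "RPKM, LPS 1 h",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Paired nascent vs mRNA fold-change dot plot
#'
#' @param pairs The `pairs` tibble from [compare_transcription_vs_mrna()].
#' @return A ggplot object.
#' @export
plot_fold_comparison <- function(pairs) {
  ggplot2::ggplot(pairs,
                  ggplot2::aes(x = .data$nascent_fold, y = .data$mrna_fold,
                               colour = .data$nascent_label)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::scale_colour_manual(values = c(
      induced = "forestgreen", silenced = "firebrick",
      unchanged = "grey30", not_expressed = "grey80")) +
    ggplot2::labs(x = "nascent fold change (signed)",
                  y = "mRNA fold change (signed)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Motif-enrichment z-score heat map
#'
#' @param heatmap A z matrix from [enrichment_heatmap()].
#' @return A ggplot object.
#' @export
plot_enrichment_heatmap <- function(heatmap) {
  df <- as_tibble(heatmap, rownames = "motif_id")
  df <- tidyr::pivot_longer(df, -"motif_id", names_to = "gene_set",
                            values_to = "z")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_set, y = .data$motif_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
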