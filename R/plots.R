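#' Plot per-condition pair correlations
#'
#' One point per condition: the Pearson correlation of convergent-pair
#' expression, annotated with the permutation p-value. Anti-regulation shows
#' as points below the zero line.
#'
#' @param object A `conv_cor` object from [correlate_all_conditions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conv_cor
#' @export
autoplot.conv_cor <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p=%.3g", .data$p_perm)),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "condition", y = "Pearson r (up vs down partner)",
                  title = "Convergent-pair expression correlation by condition") +
    ggplot2::theme_minimal()
}

#' Overlap-length distribution by pair class
#'
#' @param pairs A pair tibble from [classify_pairs()].
#' @param measure `"transcript"` (default) or `"utr"` overlap.
#' @return A ggplot histogram, faceted by class.
#' @export
plot_overlap_distribution <- function(pairs, measure = c("transcript", "utr")) {
  measure <- match.arg(measure)
  col <- if (measure == "transcript") "transcript_overlap_bp" else "utr_overlap_bp"
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = paste0(measure, " overlap (bp)"), y = "pairs") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a gene pair across single cells
#'
#' @param cell_expr A two-gene expression tibble (see
#'   [single_cell_pair_correlation()]).
#' @return A ggplot of per-cell log2 expression, gene 2 against gene 1, with
#'   a least-squares trend line.
#' @export
plot_single_cell_pair <- function(cell_expr) {
  if (nrow(cell_expr) != 2) abort("expected exactly 2 genes")
  m <- as.matrix(cell_expr[, -1])
  d <- tibble(x = m[1, ], y = m[2, ])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = paste0(cell_expr$gene_id[1], " (log2)"),
                  y = paste0(cell_expr$gene_id[2], " (log2)")) +
    ggplot2::theme_minimal()
}
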