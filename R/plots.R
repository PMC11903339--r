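# ggplot2 views of the main result types.

#' Plot average channel fractions of significant features
#'
#' @param fractions output of [channel_fractions()].
#' @return a ggplot.
#' @export
plot_channel_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$channel, y = .data$fraction,
                               fill = .data$channel)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "mean normalized fraction of significant features") +
    ggplot2::theme_minimal()
}

#' Plot granularity spectrum traces
#'
#' Thin lines per gene with the group mean in bold.
#'
#' @param spectrum output of [granularity_spectrum()].
#' @return a ggplot.
#' @export
plot_granularity_spectrum <- function(spectrum) {
  genes <- spectrum[spectrum$gene != ".mean", ]
  mean_tr <- spectrum[spectrum$gene == ".mean", ]
  ggplot2::ggplot(genes, ggplot2::aes(x = .data$size, y = .data$value,
                                      group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = mean_tr, linewidth = 1.3, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = unique(genes$size)) +
    ggplot2::labs(x = "granularity size index", y = "normalized profile value") +
    ggplot2::theme_minimal()
}

#' Plot within-complex versus background correlation distributions
#'
#' @param cc output of [complex_correlations()].
#' @return a ggplot.
#' @export
plot_complex_correlations <- function(cc) {
  df <- bind_rows(
    mutate(cc$within[, "r", drop = FALSE], set = "within complex"),
    mutate(cc$background[, "r", drop = FALSE], set = "all hit pairs")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "profile Pearson correlation", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot link-score distributions by correlation bin
#'
#' @param binned output of [binned_pair_scores()].
#' @return a ggplot.
#' @export
plot_binned_pair_scores <- function(binned) {
  binned$bin_label <- sprintf("(%.2f, %.2f]", binned$bin_lo, binned$bin_hi)
  binned$bin_label <- stats::reorder(binned$bin_label, binned$bin)
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin_label, y = .data$score)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "profile correlation bin", y = "pair link score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a diagonally merged comparative matrix
#'
#' @param object a `merged_heatmap` from [diagonal_merge()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.merged_heatmap <- function(object, ...) {
  M <- object$matrix
  df <- tidyr::expand_grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
  df$r <- M[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "screen B (upper triangle)", y = "screen A (lower triangle)",
                  fill = "r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
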