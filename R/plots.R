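#' Plot a clustering's size distribution
#'
#' @param object a `tx_clustering`.
#' @param ... unused.
#' @return A ggplot: histogram of cluster sizes (log10 x-scale when the
#'   sizes span more than a decade).
#' @method autoplot tx_clustering
#' @export
autoplot.tx_clustering <- function(object, ...) {
  sizes <- tibble::tibble(
    size = lengths(lapply(object$clusters, `[[`, "read_id")))
  p <- ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::labs(x = "reads per cluster", y = "clusters",
                  title = sprintf("%s-level clustering (%d clusters)",
                                  object$level, nrow(sizes))) +
    ggplot2::theme_minimal()
  if (nrow(sizes) && max(sizes$size) / max(min(sizes$size), 1) > 10)
    p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a read-support sweep
#'
#' Recall, precision and read-precision of one feature class as a
#' function of the minimum read support of the predictions.
#'
#' @param sweep a [support_sweep()] table.
#' @param feature_class which class to show (default `"introns"`).
#' @return A ggplot.
#' @export
plot_support_sweep <- function(sweep, feature_class = "introns") {
  d <- sweep[sweep$feature_class == feature_class, , drop = FALSE]
  d <- tidyr::pivot_longer(d, c("recall", "precision", "read_precision"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(recall = "forestgreen",
                                            precision = "firebrick",
                                            read_precision = "steelblue")) +
    ggplot2::labs(x = "minimum read support", y = NULL,
                  title = feature_class) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' Plot estimated against true transcript abundances
#'
#' @param transcriptome a [finalize_transcripts()] / [polish_quantify()]
#'   tibble.
#' @param truth_counts tibble with `transcript_id` and true `n_reads`,
#'   matched to transcripts by best sequence assignment upstream; here the
#'   rows are matched by position after sorting both by abundance.
#' @return A ggplot of estimated vs true counts on log10 axes.
#' @export
plot_abundance <- function(transcriptome, truth_counts) {
  d <- tibble::tibble(
    true = sort(truth_counts$n_reads, decreasing = TRUE),
    estimated = sort(transcriptome$abundance, decreasing = TRUE)[
      seq_len(nrow(truth_counts))])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "true read count", y = "estimated read count") +
    ggplot2::theme_minimal()
}
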