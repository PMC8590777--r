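#' Waterfall plot of repeat-tract compositions
#'
#' One horizontal bar per read, longest tract on top, segments coloured
#' by motif class (unit, interruption, insertion, other) — the standard
#' rendering of repeat structure across molecules.
#'
#' @param wt Table from [waterfall_table()].
#' @return A ggplot object.
#' @export
plot_waterfall <- function(wt) {
  ggplot2::ggplot(wt) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$start + .data$length,
      ymin = -.data$rank - 0.4, ymax = -.data$rank + 0.4,
      fill = .data$class)) +
    ggplot2::labs(x = "repeat tract position (bases)", y = "reads",
                  fill = "motif class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Per-read repeat copy-number plot
#'
#' Histogram of relative copy-number calls per sample, the usual view of
#' repeat-size distributions and somatic instability across molecules.
#'
#' @param calls Phased call tibble (from [phase_alleles()]); a `sample`
#'   column is used for facetting when present.
#' @param binwidth Histogram bin width in copy units.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(calls, binwidth = 10) {
  p <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$rel_change,
                                           fill = .data$allele)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "copy-number change vs reference", y = "reads",
                  fill = "allele") +
    ggplot2::theme_minimal()
  if ("sample" %in% names(calls)) {
    p <- p + ggplot2::facet_wrap(~sample, ncol = 1)
  }
  p
}

#' Percent-methylation profile along the locus
#'
#' @param calls Call tibble from [call_methylation()] (one sample), or
#'   several bound together with a `sample` column.
#' @return A ggplot object: percent methylation per CpG position.
#' @export
plot_methylation_profile <- function(calls) {
  p <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$pos + 1,
                                           y = 100 * .data$percent)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "position (1-based)", y = "% methylation") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if ("sample" %in% names(calls)) {
    p <- p + ggplot2::facet_wrap(~sample, ncol = 1)
  }
  p
}

#' Cumulative replication cycle time curves
#'
#' @param tracks One or more kinetics tracks (rows bound together) with
#'   the `cumulative` column from [cumulative_cycle_time()].
#' @return A ggplot object: cumulative frames against allele position,
#'   coloured by allele.
#' @export
plot_kinetics <- function(tracks) {
  ggplot2::ggplot(tracks, ggplot2::aes(x = .data$cumulative,
                                       y = .data$pos,
                                       colour = .data$allele)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "cumulative replication cycle time (frames)",
                  y = "allele position (bases)", colour = "allele") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.methyl_pca <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   label = .data$sample)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.methyl_cor <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "red") +
    ggplot2::labs(
      x = paste0("% methylation, ", object$sample_a),
      y = paste0("% methylation, ", object$sample_b),
      subtitle = sprintf("Pearson's r = %.3f", object$estimate)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
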