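#' Plot a discordance profile
#'
#' Per-position proportion of reads differing from the consensus, with the
#' polymorphism threshold drawn as a horizontal line: points above the line
#' likely represent variation among repeat copies, points below it
#' sequencing error.
#'
#' @param profile A [discordance_profile()] tibble.
#' @param threshold Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_discordance <- function(profile, threshold = 0.02) {
  d <- profile[!is.na(profile$proportion), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$proportion)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, colour = "steelblue") +
    ggplot2::labs(x = "position (bp)", y = "proportion of differing reads") +
    ggplot2::theme_minimal()
}

#' Plot a gene coverage distribution
#'
#' Box plot of per-gene coverage with the upper whisker at 1.5 times the
#' interquartile range; points above it are the flagged outliers.
#'
#' @param records Tibble from [gene_coverage()] or
#'   `tidy()` of a [summarize_gene_coverage()] object.
#' @return A ggplot object.
#' @export
plot_gene_coverage <- function(records) {
  d <- records[records$n_unique_hits > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$coverage)) +
    ggplot2::geom_boxplot(coef = 1.5, width = 0.3, outlier.size = 0.7) +
    ggplot2::labs(x = NULL, y = "estimated coverage (fold)") +
    ggplot2::theme_minimal()
}

#' Plot compartment read fractions
#'
#' @param summary Summary tibble from [classify_reads()].
#' @return A ggplot object.
#' @export
plot_compartments <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$compartment, -.data$fraction),
                               y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of reads") +
    ggplot2::theme_minimal()
}
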