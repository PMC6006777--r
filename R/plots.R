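# ggplot2 views of the main result types

#' @importFrom ggplot2 ggplot aes geom_histogram geom_point geom_line
#'   geom_col geom_errorbar geom_hline geom_vline labs scale_y_log10
#'   autoplot facet_wrap theme_minimal position_dodge
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' P-value histogram of a scan
#'
#' A calibrated null scan is flat; an excess near zero is signal (or
#' inflation -- check the GIF plot).
#'
#' @param object An `ecpg_scan` result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecpg_scan <- function(object, bins = 50, ...) {
  ggplot(as_tibble(object), aes(x = .data$p)) +
    geom_histogram(bins = bins, boundary = 0, fill = "grey35") +
    labs(x = "p-value", y = "CpG-transcript pairs") +
    theme_minimal()
}

#' Per-transcript genomic inflation factors
#'
#' @param gif Tibble from [compute_gif()].
#' @param gif_max Filter threshold drawn as a reference line.
#' @return A ggplot.
#' @export
plot_gif <- function(gif, gif_max = 2) {
  ggplot(gif, aes(x = .data$gif)) +
    geom_histogram(bins = 40, fill = "grey35") +
    geom_vline(xintercept = c(1, gif_max), linetype = c("dashed", "solid")) +
    labs(x = "genomic inflation factor", y = "transcripts") +
    theme_minimal()
}

#' Neighbor congruence across window sizes
#'
#' @param congruence Tibble from [neighbor_congruence()].
#' @return A ggplot of the three nested fractions against window size.
#' @export
plot_congruence <- function(congruence) {
  long <- tidyr::pivot_longer(
    congruence,
    c("frac_share_gene", "frac_share_gene_and_sign", "frac_all_congruent"),
    names_to = "metric", values_to = "fraction"
  )
  ggplot(long, aes(x = .data$window, y = .data$fraction, colour = .data$metric)) +
    geom_line() +
    geom_point() +
    labs(x = "window (bp)", y = "fraction of eCpGs with a neighbor") +
    theme_minimal()
}

#' Odds-ratio forest plot of enrichment results
#'
#' @param enrichment Tibble of [fisher_enrichment()] rows with a labelling
#'   column (first non-numeric column is used).
#' @return A ggplot with 95% CI error bars on a log scale.
#' @export
plot_enrichment <- function(enrichment) {
  lab <- names(enrichment)[vapply(enrichment, is.character, logical(1))][1]
  if (is.na(lab)) {
    enrichment$label <- paste0("table_", seq_len(nrow(enrichment)))
    lab <- "label"
  }
  ggplot(enrichment, aes(x = .data$odds_ratio, y = .data[[lab]])) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$ci_low, xmax = .data$ci_high), width = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "odds ratio (95% CI)", y = NULL) +
    theme_minimal()
}

#' Fraction of negative correlations per gene-body subregion
#'
#' @param sign_fractions Tibble from [genebody_sign_enrichment()].
#' @return A ggplot bar chart.
#' @export
plot_sign_fractions <- function(sign_fractions) {
  ggplot(sign_fractions, aes(x = .data$region, y = .data$frac_negative)) +
    geom_col(fill = "grey35") +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = NULL, y = "fraction negatively correlated") +
    theme_minimal()
}

#' Relative eCpG proportion by distance bin
#'
#' @param ratios Tibble from [relative_proportion_by_distance()].
#' @return A ggplot.
#' @export
plot_relative_proportion <- function(ratios) {
  ratios <- mutate(ratios, mid = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot(ratios, aes(x = .data$mid, y = .data$ratio)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "distance to associated gene (bp)", y = "relative eCpG proportion") +
    theme_minimal()
}
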