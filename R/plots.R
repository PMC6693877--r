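# ggplot2 views of the main result types. All plots are thin layers over
# the numeric tables from report_tables() and the tidiers.

#' Plot modification-level distributions
#'
#' Density of beta values per modification type (5mC bimodal, 5hmC low
#' unimodal), optionally faceted by tissue.
#'
#' @param profile A `modification_profile`.
#' @param by_tissue Facet by tissue, default `TRUE`.
#' @return A ggplot.
#' @export
plot_beta_distributions <- function(profile, by_tissue = TRUE) {
  long <- tidy(profile) %>%
    tidyr::pivot_longer(c("beta_5mc", "beta_5hmc"),
                        names_to = "modification", values_to = "beta") %>%
    mutate(modification = if_else(.data$modification == "beta_5mc", "5mC", "5hmC"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$beta,
                                          colour = .data$modification)) +
    ggplot2::geom_density(adjust = 0.5) +
    ggplot2::labs(x = expression(beta), y = "density", colour = NULL) +
    ggplot2::theme_minimal()
  if (by_tissue) p <- p + ggplot2::facet_wrap(~tissue)
  p
}

#' Plot the per-CpG 5mC-5hmC correlation distribution
#'
#' @param correlations Tibble from [per_cpg_correlation()].
#' @return A ggplot histogram of Pearson r with a zero reference line.
#' @export
plot_correlation_histogram <- function(correlations) {
  ggplot2::ggplot(dplyr::filter(correlations, !.data$degenerate),
                  ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "per-CpG Pearson r (5mC vs 5hmC)", y = "CpGs") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment odds-ratio panel
#'
#' Log2 odds ratios per annotation label with the one-sided Fisher p as
#' point colour; infinite odds ratios are drawn at the panel edge.
#'
#' @param enrichment Tibble from [enrichment_table()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  d <- enrichment %>%
    mutate(log2_or = log2(pmin(pmax(.data$odds_ratio, 2^-8), 2^8)),
           label = stats::reorder(.data$label, .data$log2_or))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_or, y = .data$label,
                                  colour = -log10(pmax(.data$p_one_sided, 1e-300)))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(log[2] ~ "odds ratio"), y = NULL,
                  colour = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the null gene-hit counts with the observed count as a
#' vertical line, the usual display for permutation gene-set tests.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey55") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "target genes hit (null draws)", y = "permutations",
      title = sprintf("observed = %d, empirical p = %.4g (%d permutations)",
                      object$observed, object$empirical_p, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Heatmap of M-values for selected loci
#'
#' @param mvalues Probes x units M-value matrix (from [report_tables()]).
#' @return A ggplot tile heatmap, probes ordered by hierarchical
#'   clustering when there are at least 3.
#' @export
plot_mvalue_heatmap <- function(mvalues) {
  ord <- if (nrow(mvalues) >= 3)
    stats::hclust(stats::dist(mvalues))$order else seq_len(nrow(mvalues))
  long <- tibble(probe_id = factor(rep(rownames(mvalues)[ord], ncol(mvalues)),
                                   levels = rownames(mvalues)[ord]),
                 unit = rep(colnames(mvalues), each = nrow(mvalues)),
                 m = as.vector(mvalues[ord, , drop = FALSE]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$unit, y = .data$probe_id,
                                     fill = .data$m)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "M") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
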