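#' @name rtk-plots
#' @title ggplot2 views of pipeline results
NULL

#' @importFrom ggplot2 ggplot aes geom_histogram geom_vline geom_col
#'   geom_point geom_abline labs theme_minimal scale_x_continuous autoplot
NULL

#' @export
ggplot2::autoplot

#' Histogram of the random-topology null with the observed count
#'
#' @param object An `rtk_null` from [random_topology_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rtk_null <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$known_pairs)) +
    geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$observed, colour = "firebrick",
               linewidth = 0.8) +
    labs(x = "known bait-prey pairs per random network", y = "iterations",
         title = sprintf("observed %d vs null mean %.2f (p = %.2g)",
                         object$observed, object$mean, object$empirical_p)) +
    theme_minimal()
}

#' Bar chart of HCIs by number of supporting known-interaction sources
#'
#' @param histogram Tibble from [known_source_histogram()].
#' @return A ggplot.
#' @export
plot_known_sources <- function(histogram) {
  ggplot(histogram, aes(x = factor(.data$n_sources), y = .data$n_hcis)) +
    geom_col(fill = "steelblue") +
    labs(x = "supporting source databases", y = "high-confidence interactors") +
    theme_minimal()
}

#' Dot plot of enrichment results
#'
#' @param enrichment Tibble from [fisher_enrichment()].
#' @param top Number of top terms (by q) to show.
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, top = 20L) {
  df <- head(enrichment, top)
  df$term <- factor(df$term_id, levels = rev(df$term_id))
  ggplot(df, aes(x = .data$log2_fc, y = .data$term,
                 size = .data$k, colour = -log10(.data$q + 1e-300))) +
    geom_point() +
    labs(x = "log2 fold change", y = NULL, size = "hits",
         colour = "-log10 q") +
    theme_minimal()
}

#' Scatter of shared-pair average counts between two conditions
#'
#' @param comparison An `rtk_condition_comparison` from
#'   [compare_conditions()].
#' @return A ggplot.
#' @export
plot_condition_comparison <- function(comparison) {
  ggplot(comparison$shared,
         aes(x = .data$avg_count_b, y = .data$avg_count_a)) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    labs(x = sprintf("average count (%s)", comparison$labels[2]),
         y = sprintf("average count (%s)", comparison$labels[1]),
         title = sprintf("Pearson r = %s",
                         ifelse(is.na(comparison$r), "NA",
                                format(round(comparison$r, 3))))) +
    theme_minimal()
}
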