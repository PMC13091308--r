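# ggplot2 visualisations for the main result types.

#' Running enrichment-score profile
#'
#' The GSEA running sum along the ranking, with hit positions marked and
#' the extremum (the enrichment score) highlighted.
#'
#' @param ranked A `ranked_list`.
#' @param set_genes Member gene ids.
#' @param weight_exponent Weighting exponent (default 1).
#' @return A ggplot object.
#' @export
plot_enrichment_profile <- function(ranked, set_genes, weight_exponent = 1) {
  es <- enrichment_score(ranked, set_genes, weight_exponent)
  hits <- es$profile[es$profile$gene %in% set_genes, ]
  ggplot2::ggplot(es$profile, ggplot2::aes(x = .data$pos,
                                           y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = hits, sides = "b", colour = "grey30",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::geom_vline(xintercept = es$extremum_pos, linetype = "dashed",
                        colour = "#d95f02") +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", es$es)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_enrichment_profile NES bar chart for a GSEA run.
#' @param object A `gsea_results` tibble.
#' @param ... Unused.
#' @export
autoplot.gsea_results <- function(object, ...) {
  d <- object[is.na(object$skipped), ]
  d$significant <- d$fdr_q < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$set, .data$nes),
                                  y = .data$nes,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d95f02",
                                          `FALSE` = "grey60"),
                               name = "FDR < 0.05") +
    ggplot2::labs(x = NULL, y = "normalized enrichment score") +
    ggplot2::theme_minimal()
}

#' Forest plot of partitioned heritability enrichment
#'
#' Enrichment ratios with +/- 1.96 SE jackknife intervals; the vertical
#' line at 1 marks no enrichment.
#'
#' @param object A `partitioned_h2` tibble.
#' @param ... Unused.
#' @export
autoplot.partitioned_h2 <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$enrichment,
                                  y = stats::reorder(.data$annotation,
                                                     .data$enrichment))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$enrichment - 1.96 * .data$se_jackknife,
      xmax = .data$enrichment + 1.96 * .data$se_jackknife), height = 0.2) +
    ggplot2::geom_point(colour = "#2c7fb8", size = 2) +
    ggplot2::labs(x = "heritability enrichment", y = NULL) +
    ggplot2::theme_minimal()
}

#' TWAS gene Z by tissue
#'
#' Absolute gene Z-scores per tissue with the per-tissue FDR-significant
#' genes highlighted.
#'
#' @param object A `twas_results` tibble.
#' @param fdr_threshold Highlight threshold on the per-tissue q (default
#'   0.05).
#' @param ... Unused.
#' @export
autoplot.twas_results <- function(object, fdr_threshold = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$significant <- d$q < fdr_threshold
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tissue, y = abs(.data$z),
                                  colour = .data$significant)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02",
                                            `FALSE` = "grey60"),
                                 name = sprintf("q < %.2g", fdr_threshold)) +
    ggplot2::labs(x = NULL, y = "|gene Z|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
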