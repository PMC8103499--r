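# Summary plots: per-class distribution panels and correlation heatmaps,
# mirroring the figures this kind of comparative analysis usually reports.

#' Distribution of a per-gene statistic across duplicate-gene classes
#'
#' Boxplots of one statistic for each gene class next to the overall
#' distribution.
#'
#' @param gene_stats long tibble (`gene_id`, `statistic`, `value`).
#' @param classes tibble (`gene_id`, `class`).
#' @param statistic which statistic to plot.
#' @return a ggplot object.
#' @export
plot_class_distributions <- function(gene_stats, classes, statistic) {
  sv <- gene_stats |>
    filter(.data$statistic == !!statistic, !is.na(.data$value))
  df <- bind_rows(
    sv |> mutate(class = "overall"),
    sv |> inner_join(classes, by = "gene_id",
                     relationship = "many-to-many"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of sample-profile Spearman correlations
#'
#' @param correlations tibble from [sample_profile_correlations()] (one
#'   context) or [subgenome_asymmetry()]`$correlations` (columns ending in
#'   1/2 plus `rho`).
#' @return a ggplot object.
#' @export
plot_correlation_heatmap <- function(correlations) {
  nm <- names(correlations)
  c1 <- intersect(c("sample1", "profile1"), nm)[1]
  c2 <- intersect(c("sample2", "profile2"), nm)[1]
  df <- correlations |>
    transmute(a = .data[[c1]], b = .data[[c2]], rho = .data$rho)
  df <- bind_rows(df, df |> rename(a = "b", b = "a"),
                  tibble(a = unique(c(df$a, df$b)),
                         b = unique(c(df$a, df$b)), rho = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.dupevol_asymmetry <- function(object, ...) {
  d <- object$per_gene_species |>
    group_by(.data$pair_id) |>
    filter(dplyr::n() >= 2) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species, y = .data$pair_id,
                                  fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", high = "darkred",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = NULL, y = "doublet pair",
                  fill = "A - B level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
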