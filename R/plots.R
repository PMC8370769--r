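# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_tile geom_step geom_line geom_ribbon
#'   geom_col geom_point labs scale_fill_gradient2 theme_minimal facet_wrap
#'   autoplot
NULL

#' Plot a clustered trajectory heatmap
#'
#' Features (rows, in dendrogram order) by stages, filled by scaled value,
#' faceted by flat cluster.
#'
#' @param object A `phos_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phos_clusters <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  df <- object$trajectories |>
    inner_join(object$assignments, by = "feature_id") |>
    tidyr::pivot_longer(all_of(object$stages), names_to = "stage",
                        values_to = "value") |>
    mutate(
      feature_id = factor(.data$feature_id, levels = ord),
      stage = factor(.data$stage, levels = object$stages)
    )
  ggplot(df, aes(x = .data$stage, y = .data$feature_id, fill = .data$value)) +
    geom_tile() +
    facet_wrap(~cluster, scales = "free_y") +
    scale_fill_gradient2(low = "#313695", mid = "#ffffbf", high = "#a50026",
                         midpoint = 0.5, name = "scaled") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    labs(x = NULL, y = NULL, title = "Scaled phosphorylation trajectories")
}

#' Plot cumulative dephosphorylation distributions
#'
#' Empirical CDFs of the per-site MI-to-MII deltas by group (SP, TP,
#' +2 classes).
#'
#' @param object An `sp_tp_result`.
#' @param groups Optional subset of group labels to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sp_tp_result <- function(object, groups = NULL, ...) {
  df <- object$cdf
  if (!is.null(groups)) df <- filter(df, .data$group %in% groups)
  ggplot(df, aes(x = .data$delta, y = .data$cdf, colour = .data$group)) +
    geom_step() +
    theme_minimal() +
    labs(x = paste0("scaled ", object$from, " - ", object$to, " delta"),
         y = "cumulative fraction", colour = NULL,
         title = "Dephosphorylation across the transition")
}

#' Plot a positional enrichment matrix
#'
#' Offset-by-residue tiles filled by percent frequency difference;
#' significant calls outlined.
#'
#' @param object A `motif_enrichment` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(residue = factor(.data$residue, levels = rev(AA20)))
  ggplot(df, aes(x = .data$offset, y = .data$residue, fill = .data$pct_diff)) +
    geom_tile() +
    geom_point(data = filter(df, .data$call != "none"),
               ggplot2::aes(shape = .data$call), size = 1) +
    scale_fill_gradient2(low = "#2166ac", high = "#b2182b", name = "% diff") +
    theme_minimal() +
    labs(x = "offset from phosphosite", y = NULL,
         title = "Selected / deselected residues")
}

#' Plot per-stage peak fractions
#'
#' @param stage_summary A [stage_summaries()] tibble.
#' @param stages Stage order.
#' @return A ggplot.
#' @export
plot_peak_fractions <- function(stage_summary, stages = stage_summary$stage) {
  df <- mutate(stage_summary, stage = factor(.data$stage, levels = stages))
  ggplot(df, aes(x = .data$stage, y = .data$peak_fraction)) +
    geom_col(fill = "#4393c3") +
    theme_minimal() +
    labs(x = NULL, y = "fraction of sites peaking",
         title = "Peak phosphorylation stage")
}

#' Plot an occupancy trajectory with its spread
#'
#' Mean +/- sd per stage, e.g. the RVxF occupancy trace from
#' [rvxf_occupancy()].
#'
#' @param trace Tibble with `stage`, `mean`, `sd`.
#' @param stages Stage order.
#' @return A ggplot.
#' @export
plot_occupancy_trace <- function(trace, stages = trace$stage) {
  df <- mutate(trace, stage = factor(.data$stage, levels = stages),
               x = as.integer(.data$stage))
  ggplot(df, aes(x = .data$x, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                fill = "#c6dbef") +
    geom_line(colour = "#2171b5") +
    ggplot2::scale_x_continuous(breaks = df$x, labels = levels(df$stage)) +
    theme_minimal() +
    labs(x = NULL, y = "scaled phosphorylation",
         title = "Mean occupancy trajectory")
}

#' Plot the protein abundance distribution
#'
#' @param object An `abundance_dist` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abundance_dist <- function(object, ...) {
  ggplot(object$data, aes(x = .data$log10_intensity)) +
    ggplot2::geom_histogram(bins = max(10, nrow(object$histogram)),
                            fill = "#74add1", colour = "white") +
    theme_minimal() +
    labs(x = "log10 summed intensity", y = "proteins",
         title = "Protein abundance distribution")
}
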