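#' Bubble chart of an enrichment result
#'
#' Gene ratio on x, terms ordered by significance on y, point size the overlap
#' count, colour the adjusted p-value — the conventional enrichment bubble
#' chart.
#'
#' @param object An `np_enrich` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.np_enrich <- function(object, ...) {
  df <- as_tibble(unclass(object))
  df$term_name <- factor(df$term_name,
                         levels = rev(unique(df$term_name[order(df$p_value)])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_ratio, y = .data$term_name,
                                   size = .data$k,
                                   colour = .data$p_adjusted)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#b2182b", high = "#2166ac") +
    ggplot2::labs(x = "Gene ratio (k / n)", y = NULL, size = "Overlap",
                  colour = "Adjusted p") +
    ggplot2::theme_minimal()
}

#' Centrality scatter of a PPI analysis
#'
#' Degree versus normalised betweenness, coloured by key-target status, with
#' the screening thresholds drawn as reference lines.
#'
#' @param object An `np_ppi` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.np_ppi <- function(object, ...) {
  th <- object$thresholds
  ggplot2::ggplot(object$centrality,
                  ggplot2::aes(x = .data$degree, y = .data$betweenness,
                               colour = .data$is_key)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$closeness), size = 3) +
    ggplot2::geom_vline(xintercept = th[["deg_min"]], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = th[["bc_min"]], linetype = "dashed") +
    ggplot2::labs(x = "Degree", y = "Betweenness (normalised)",
                  colour = "Key target", alpha = "Closeness") +
    ggplot2::theme_minimal()
}

#' Layered degree plot of a tripartite network
#'
#' Node degree by layer, top nodes per layer labelled by rank order.
#'
#' @param object An `np_ctp` object.
#' @param top_n Nodes shown per layer; default 10.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.np_ctp <- function(object, top_n = 10, ...) {
  df <- degree_table(object)
  df <- dplyr::slice_head(dplyr::group_by(df, .data$layer), n = top_n)
  df <- dplyr::ungroup(df)
  df$node <- factor(df$node, levels = rev(unique(df$node)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$node,
                                   fill = .data$layer)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$layer), scales = "free_y") +
    ggplot2::labs(x = "Degree", y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
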