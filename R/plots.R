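#' Enrichment bubble chart
#'
#' Gene ratio on the x axis, terms on the y axis, bubble size the enriched
#' gene count and colour the p-value — the standard over-representation
#' summary figure, faceted by annotation category.
#'
#' @param rows An [ora()] result (typically after [select_top()]).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows) {
  dat <- bubble_export(rows)
  if (nrow(dat) == 0) stop("no enrichment rows to plot", call. = FALSE)
  dat$term_name <- stats::reorder(dat$term_name, dat$count)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene_ratio, y = .data$term_name,
                                    size = .data$count, colour = .data$p_value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "count", colour = "p-value") +
    ggplot2::theme_bw()
}

#' @export
autoplot.phytonet_ora <- function(object, ...) plot_enrichment(object)

#' Degree distribution of a typed graph
#'
#' Bar chart of node degree coloured by role; the usual first look at a
#' compound-target or protein-interaction network.
#'
#' @param g A `typed_graph`.
#' @param top_n Show only the `top_n` highest-degree nodes (default 30).
#' @return A ggplot object.
#' @export
plot_degree <- function(g, top_n = 30) {
  cent <- centrality(g) |>
    dplyr::arrange(dplyr::desc(.data$degree)) |>
    dplyr::slice_head(n = top_n)
  cent$id <- stats::reorder(cent$id, cent$degree)
  ggplot2::ggplot(cent, ggplot2::aes(x = .data$degree, y = .data$id,
                                     fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "degree", y = NULL) +
    ggplot2::theme_bw()
}

#' @export
autoplot.typed_graph <- function(object, ...) plot_degree(object, ...)

#' Degree versus betweenness of compound nodes
#'
#' Visualizes the main-ingredient screen: compound nodes plotted by degree
#' and betweenness with the two means as dashed lines; the upper-right
#' quadrant is the selected set.
#'
#' @param screen A [screen_main_ingredients()] result.
#' @return A ggplot object.
#' @export
plot_ingredient_screen <- function(screen) {
  ggplot2::ggplot(screen$table,
                  ggplot2::aes(x = .data$degree, y = .data$betweenness,
                               colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = screen$mean_degree, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = screen$mean_betweenness, linetype = "dashed") +
    ggplot2::labs(x = "degree", y = "betweenness centrality",
                  colour = "selected") +
    ggplot2::theme_bw()
}

#' @export
autoplot.phytonet_ingredients <- function(object, ...) plot_ingredient_screen(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
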