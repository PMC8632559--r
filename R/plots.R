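#' Stacked relative information flow across conditions
#'
#' @param rel_flow Output of [relative_information_flow()].
#' @return A ggplot: one bar per pathway, filled by condition share.
#' @export
plot_information_flow <- function(rel_flow) {
  df <- filter(as_tibble(rel_flow), !.data$undefined)
  ggplot2::ggplot(df, ggplot2::aes(.data$rel_flow, .data$pathway,
                                   fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative information flow", y = NULL, fill = "condition") +
    ggplot2::theme_minimal()
}

#' Heatmap of differential interaction counts
#'
#' Red marks sender-receiver pairs with more significant ligand-receptor
#' interactions in the second condition, blue fewer.
#'
#' @param diff_counts Output of [differential_counts()].
#' @return A ggplot.
#' @export
plot_differential_counts <- function(diff_counts) {
  ggplot2::ggplot(as_tibble(diff_counts),
                  ggplot2::aes(.data$receiver, .data$sender, fill = .data$delta_n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::labs(x = "receiver", y = "sender", fill = "Δ interactions") +
    ggplot2::theme_minimal()
}

#' Layered layout plot of a multiscale signaling graph
#'
#' Nodes are arranged on four vertical layers (ligand, receptor, TF, target)
#' and edges drawn with width proportional to weight; dashed edges mark
#' repression.
#'
#' @param object,x A `multiscale_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.multiscale_graph <- function(object, ...) {
  nodes <- graph_nodes(object)
  layer_x <- c(ligand = 1, receptor = 2, tf = 3, target = 4)
  nodes <- nodes |>
    group_by(.data$role) |>
    mutate(x = layer_x[.data$role[1]],
           y = seq_len(n()) / (n() + 1)) |>
    ungroup()
  edges <- as_tibble(object) |>
    left_join(select(nodes, from = "node", x0 = "x", y0 = "y"),
              by = "from", relationship = "many-to-many") |>
    left_join(select(nodes, to = "node", x1 = "x", y1 = "y"),
              by = "to", relationship = "many-to-many") |>
    filter(.data$x1 == .data$x0 + 1)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linewidth = .data$weight,
                                       linetype = factor(.data$sign)),
                          color = "grey50", alpha = 0.7) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       vjust = -0.7, size = 3) +
    ggplot2::scale_x_continuous(breaks = layer_x, labels = names(layer_x),
                                limits = c(0.5, 4.5)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::scale_linetype_manual(values = c(`-1` = "dashed", `1` = "solid")) +
    ggplot2::labs(x = NULL, y = NULL, linetype = "sign", linewidth = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @export
plot.multiscale_graph <- function(x, ...) print(autoplot.multiscale_graph(x, ...))
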