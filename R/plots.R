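#' Plot per-level growth of a decomposition
#'
#' Cumulative node and edge counts by expansion level, with the newly
#' added counts as bars — the shape of the curve shows how quickly the
#' network saturates around the skeleton.
#'
#' @param object A `level_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot level_decomposition
#' @export
autoplot.level_decomposition <- function(object, ...) {
  pl <- object$per_level
  long <- tidyr::pivot_longer(
    pl[, c("level", "total_nodes", "total_edges")],
    cols = c("total_nodes", "total_edges"),
    names_to = "quantity", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$count,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "expansion level", y = "cumulative count (log scale)",
                  colour = NULL,
                  title = "Network growth by expansion level") +
    ggplot2::theme_minimal()
}

#' Plot in/out degree histograms
#'
#' @param object A `graph_stats` row from [compute_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot graph_stats
#' @export
autoplot.graph_stats <- function(object, ...) {
  h <- bind_rows(
    mutate(object$in_degree_hist[[1]], direction = "in-degree"),
    mutate(object$out_degree_hist[[1]], direction = "out-degree"))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "degree", y = "nodes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Plot an interaction graph
#'
#' Small-network diagnostic view: nodes positioned by a seeded
#' force-directed layout (or caller-supplied positions), coloured by level
#' when levels are set, drivers outlined; edges coloured by interaction
#' type following the field's convention (physical red, genetic blue,
#' unknown black).
#'
#' @param object An `interaction_graph`.
#' @param positions Optional `symbol`/`x`/`y` data frame; defaults to a
#'   deterministic force-directed layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_graph
#' @export
autoplot.interaction_graph <- function(object, positions = NULL, ...) {
  nodes <- graph_nodes(object)
  if (is.null(positions)) {
    ig <- as_igraph(object)
    set.seed(1L)
    xy <- igraph::layout_with_fr(ig)
    positions <- tibble(symbol = igraph::V(ig)$name,
                        x = xy[, 1], y = xy[, 2])
  } else {
    positions <- as_tibble(positions)
  }
  nd <- left_join(nodes, positions, by = "symbol")
  ed <- tidy.interaction_graph(object)
  ed <- left_join(ed, rename(positions, xend0 = "x", yend0 = "y"),
                  by = c(src = "symbol"))
  ed <- left_join(ed, rename(positions, xend1 = "x", yend1 = "y"),
                  by = c(dst = "symbol"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xend0, y = .data$yend0, xend = .data$xend1,
                   yend = .data$yend1, colour = .data$itype),
      alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.6, "mm"))) +
    ggplot2::scale_colour_manual(values = c(
      physical = "#c0392b", genetic = "#2980b9", unknown = "#2c3e50")) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$is_driver,
                   fill = level_label(.data$level)),
      size = 3, colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 23, `FALSE` = 21),
                                labels = c(`TRUE` = "driver",
                                           `FALSE` = "gene")) +
    ggplot2::geom_text(
      data = nd, ggplot2::aes(x = .data$x, y = .data$y,
                              label = .data$symbol),
      size = 2.4, vjust = -1.1) +
    ggplot2::labs(colour = "interaction", fill = "level", shape = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
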