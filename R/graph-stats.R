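#' Degree and redundancy statistics of a graph
#'
#' Each directed edge contributes one out-degree at its source and one
#' in-degree at its destination; a self-loop contributes one of each to the
#' same node. A node's degree is its in-degree plus out-degree, so the
#' identities `avg_degree == 2 * n_edges / n_nodes` and
#' `avg_in_degree == avg_out_degree == n_edges / n_nodes` hold by
#' construction. `n_nonredundant` counts distinct unordered endpoint pairs,
#' collapsing direction and parallel edge types; a self-loop counts as the
#' one pair `{A, A}`.
#'
#' @param graph An `interaction_graph`.
#' @param node_subset Optional character vector: restrict to these nodes
#'   and their induced edges.
#' @return A one-row tibble of class `graph_stats`: `n_nodes`, `n_edges`,
#'   `n_nonredundant`, `avg_degree`, `avg_in_degree`, `avg_out_degree`,
#'   plus list-columns `in_degree_hist` and `out_degree_hist`
#'   (degree/count tibbles).
#' @export
compute_stats <- function(graph, node_subset = NULL) {
  if (!is.null(node_subset)) graph <- graph_subset(graph, node_subset)
  nodes <- graph_nodes(graph)
  edges <- graph_edges(graph)
  n_nodes <- nrow(nodes)
  n_edges <- nrow(edges)
  nonred <- if (n_edges == 0) 0L else {
    length(unique(paste(pmin(edges$src, edges$dst),
                        pmax(edges$src, edges$dst), sep = "\r")))
  }
  out_deg <- table(factor(edges$src, levels = nodes$symbol))
  in_deg <- table(factor(edges$dst, levels = nodes$symbol))
  hist_of <- function(deg) {
    tab <- table(as.integer(deg))
    tibble(degree = as.integer(names(tab)), count = as.integer(tab))
  }
  res <- tibble(
    n_nodes = n_nodes,
    n_edges = n_edges,
    n_nonredundant = as.integer(nonred),
    avg_degree = if (n_nodes == 0) NA_real_ else 2 * n_edges / n_nodes,
    avg_in_degree = if (n_nodes == 0) NA_real_ else n_edges / n_nodes,
    avg_out_degree = if (n_nodes == 0) NA_real_ else n_edges / n_nodes,
    in_degree_hist = list(hist_of(in_deg)),
    out_degree_hist = list(hist_of(out_deg))
  )
  class(res) <- c("graph_stats", class(res))
  res
}

#' Driver-to-driver shortest-path distance matrix
#'
#' Directed BFS distance between every ordered pair of driver genes; the
#' backbone of connectivity summaries comparing how tightly the driver set
#' is knit together (e.g. how many pairs sit at distance one, three, ...).
#'
#' @param graph An `interaction_graph`.
#' @param drivers Optional character vector of driver symbols; defaults to
#'   the graph's drivers.
#' @return A tibble `from`, `to`, `distance` (NA when unreachable) over all
#'   ordered pairs with `from != to`.
#' @export
driver_distances <- function(graph, drivers = NULL) {
  drivers <- drivers %||% driver_symbols(graph)
  check_symbols(graph, drivers)
  adj <- adjacency_index(graph)
  rows <- map(drivers, function(a) {
    dist <- bfs_distances(adj$out, a)
    others <- setdiff(drivers, a)
    tibble(from = a, to = others, distance = as.integer(dist[others]))
  })
  bind_rows(rows)
}
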