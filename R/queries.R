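# resolve a level cap to the set of in-scope symbols; extra symbols (the
# query genes) are always admitted
scope_nodes <- function(graph, level_cap, extra = character()) {
  if (identical(level_cap, "whole") || is.infinite(level_cap)) {
    return(graph_symbols(graph))
  }
  lv <- graph_nodes(graph)$level
  if (all(is.na(lv))) {
    abort(paste0("graph has no level assignment; run expand_levels() and ",
                 "set_levels() before using a finite level cap"))
  }
  syms <- graph_nodes(graph)$symbol
  union(syms[!is.na(lv) & lv <= level_cap], extra)
}

#' Query 1: what interacts directly with the gene(s) of interest?
#'
#' Returns the induced subgraph over the query genes plus all their
#' parents and children within scope. Iterative exploration is re-calling
#' the query with a neighbor added to `genes`.
#'
#' @param graph An `interaction_graph` (levelled via [set_levels()] if a
#'   finite `level_cap` is used).
#' @param genes Character vector of query genes; all must be in the graph.
#' @param level_cap Restrict neighbors to nodes with level `<= level_cap`;
#'   `"whole"` (default) means no restriction. Query genes are always
#'   included, even outside the cap.
#' @return An `interaction_graph` subgraph.
#' @export
query_direct <- function(graph, genes, level_cap = "whole") {
  check_symbols(graph, genes)
  scope <- scope_nodes(graph, level_cap, extra = genes)
  adj <- adjacency_index(graph)
  nb <- unique(unlist(c(adj$out[genes], adj$`in`[genes]),
                      use.names = FALSE))
  keep <- union(genes, intersect(nb, scope))
  graph_subset(graph, keep)
}

#' Query 2: all shortest paths between two genes of interest
#'
#' Delegates to [all_shortest_paths()] within the level scope. Edges are
#' directed, so only paths driving from `gene_a` to `gene_b` are listed;
#' an empty result suggests re-running with the genes swapped to probe the
#' reverse direction. `gene_a == gene_b` yields the single zero-length
#' path.
#'
#' @inheritParams query_direct
#' @param gene_a,gene_b Query gene symbols.
#' @param max_paths Cap on returned paths (default 1000); when hit the
#'   result carries attribute `truncated = TRUE`.
#' @return A `path_tbl` with attributes `n_paths` and `path_length`.
#' @export
query_paths_between <- function(graph, gene_a, gene_b, level_cap = "whole",
                                max_paths = 1000) {
  check_symbols(graph, c(gene_a, gene_b))
  scope <- scope_nodes(graph, level_cap, extra = c(gene_a, gene_b))
  res <- all_shortest_paths(graph, gene_a, gene_b, allowed = scope,
                            max_paths = max_paths)
  attr(res, "n_paths") <- nrow(res)
  attr(res, "path_length") <- if (nrow(res) > 0) res$n_edges[1] else
    NA_integer_
  if (nrow(res) == 0) {
    inform(sprintf(
      "no directed path %s -> %s; try the reverse query %s -> %s",
      gene_a, gene_b, gene_b, gene_a))
  }
  res
}

#' Query 3: is a gene connected to the levelled disease network?
#'
#' Finds the shortest connections between `gene` and the set `T` of all
#' nodes with level `<= target_level` (excluding the gene itself). Because
#' the engine is directed while "connected to" is not, both orientations
#' are searched and reported separately, never merged: outbound paths
#' `gene -> T` and inbound paths `T -> gene`, each at its own minimal
#' distance, with every shortest path to every nearest target listed.
#'
#' @inheritParams query_direct
#' @param gene The query gene symbol.
#' @param target_level Integer level defining the target set; must not
#'   exceed the decomposition's saturation level.
#' @param decomposition Optional `level_decomposition`; defaults to the
#'   level assignment already on the graph (see [set_levels()]).
#' @param max_paths Cap on returned paths per direction.
#' @return A `path_tbl` with a `direction` column (`"outbound"` /
#'   `"inbound"`); empty when no connection exists in either direction.
#' @export
query_connect_to_level <- function(graph, gene, target_level,
                                   decomposition = NULL, max_paths = 1000) {
  check_symbols(graph, gene)
  if (!is.null(decomposition)) graph <- set_levels(graph, decomposition)
  lv <- graph_nodes(graph)$level
  if (all(is.na(lv))) {
    abort("graph has no level assignment; pass `decomposition` or run set_levels()")
  }
  if (!is.null(decomposition) &&
      !is.na(decomposition$saturation_level) &&
      target_level > decomposition$saturation_level) {
    abort(sprintf("target_level %d exceeds saturation level %d",
                  target_level, decomposition$saturation_level))
  }
  syms <- graph_nodes(graph)$symbol
  targets <- setdiff(syms[!is.na(lv) & lv <= target_level], gene)
  adj <- adjacency_index(graph)

  one_direction <- function(adj_fwd, adj_bwd, label) {
    dist <- bfs_distances(adj_fwd, gene)
    dt <- dist[targets]
    if (all(is.na(dt))) return(NULL)
    dstar <- min(dt, na.rm = TRUE)
    hits <- sort(targets[!is.na(dt) & dt == dstar], method = "radix")
    paths <- list()
    for (h in hits) {
      ps <- backtrack_paths(adj_bwd, dist, h, max_paths = max_paths)
      paths <- c(paths, ps)
    }
    if (length(paths) > max_paths) paths <- paths[seq_len(max_paths)]
    if (label == "inbound") paths <- map(paths, rev)
    out <- path_tibble(paths, graph)
    out$direction <- label
    out
  }
  outbound <- one_direction(adj$out, adj$`in`, "outbound")
  # inbound: BFS on the reversed graph, then flip sequences back to T -> gene
  inbound <- one_direction(adj$`in`, adj$out, "inbound")
  res <- bind_rows(outbound, inbound)
  if (nrow(res) == 0) {
    res <- path_tibble(list(), graph)
    res$direction <- character()
  }
  class(res) <- unique(c("path_tbl", class(res)))
  res
}
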