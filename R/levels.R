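#' Expand the skeleton into levels until saturation
#'
#' Level 0 is the skeleton. Each subsequent level adds all parents and
#' children of the previous level's nodes; a level's edge set is every
#' graph edge with both endpoints inside the level's node set, which
#' includes the within-level links among newly added nodes, not only the
#' spokes that recruited them. The same induced-edge rule is applied at
#' level 0, so per-level totals always reconcile with the whole graph;
#' the skeleton's shortest-path edge subset remains available in the
#' `skeleton_result`. Expansion stops at the first step that adds
#' no new node — the saturation level — or at `max_level`. Nodes never
#' reached (isolated genes and islands disconnected from the skeleton)
#' carry no level and belong to the whole graph only.
#'
#' Each node's level is its first level of appearance, which equals its
#' undirected parent/child distance from the skeleton node set.
#'
#' @param graph An `interaction_graph`.
#' @param skeleton A `skeleton_result` (its unconnected drivers are
#'   carried through) or a plain character vector of seed symbols.
#' @param max_level Optional cap on the number of expansion steps; the
#'   default expands to saturation, which always terminates because the
#'   node set is finite and grows strictly.
#' @return An object of class `level_decomposition`: list with `level_of`
#'   (tibble `symbol`, `level` — `NA` for whole-graph-only nodes —,
#'   `is_driver`, `driver_class`), `per_level` (tibble `level`,
#'   `new_nodes`, `new_edges`, `total_nodes`, `total_edges`),
#'   `saturation_level` (NA when stopped early by `max_level`),
#'   `unconnected_drivers`, and `whole` (total node/edge counts).
#' @export
expand_levels <- function(graph, skeleton, max_level = NULL) {
  unconnected <- character()
  if (inherits(skeleton, "skeleton_result")) {
    seeds <- skeleton$nodes
    unconnected <- skeleton$unconnected_drivers
  } else {
    seeds <- as.character(skeleton)
    check_symbols(graph, seeds)
  }
  edges <- graph_edges(graph)
  nodes <- graph_nodes(graph)
  adj <- adjacency_index(graph)
  undirected <- setNames(
    map(nodes$symbol, function(s) union(adj$out[[s]], adj$`in`[[s]])),
    nodes$symbol)

  level_of <- setNames(rep(NA_integer_, nrow(nodes)), nodes$symbol)
  level_of[seeds] <- 0L
  current <- seeds
  induced_count <- function(set) {
    sum(edges$src %in% set & edges$dst %in% set)
  }
  level0_edges <- induced_count(seeds)
  per_level <- list(tibble(
    level = 0L, new_nodes = length(seeds), new_edges = as.integer(level0_edges),
    total_nodes = length(seeds), total_edges = as.integer(level0_edges)))
  prev_edges <- level0_edges
  k <- 0L
  saturation <- NA_integer_
  repeat {
    if (!is.null(max_level) && k >= max_level) break
    frontier <- setdiff(
      unique(unlist(undirected[current], use.names = FALSE)), current)
    if (length(frontier) == 0) {
      saturation <- k
      break
    }
    k <- k + 1L
    level_of[frontier] <- k
    current <- c(current, frontier)
    tot_edges <- induced_count(current)
    per_level[[k + 1L]] <- tibble(
      level = k, new_nodes = length(frontier),
      new_edges = as.integer(tot_edges - prev_edges),
      total_nodes = length(current), total_edges = as.integer(tot_edges))
    prev_edges <- tot_edges
  }
  structure(
    list(
      level_of = tibble(symbol = nodes$symbol,
                        level = unname(level_of[nodes$symbol]),
                        is_driver = nodes$is_driver,
                        driver_class = nodes$driver_class),
      per_level = bind_rows(per_level),
      saturation_level = saturation,
      unconnected_drivers = unconnected,
      whole = tibble(total_nodes = nrow(nodes),
                     total_edges = nrow(edges))
    ),
    class = "level_decomposition"
  )
}

#' Nodes of a given level (cumulative)
#'
#' @param decomposition A `level_decomposition`.
#' @param level Integer level; `Inf` or `"whole"` selects every node.
#' @return Character vector of symbols with level `<= level`.
#' @export
level_nodes <- function(decomposition, level) {
  lo <- decomposition$level_of
  if (identical(level, "whole") || is.infinite(level)) return(lo$symbol)
  lo$symbol[!is.na(lo$level) & lo$level <= level]
}

#' The whole graph, reconciled against a decomposition
#'
#' The whole graph is the complete node and edge set, including
#' whole-graph-only components whose edges connect only unlevelled nodes
#' (self-referencing islands among them). Errors if the decomposition does
#' not cover the graph's node set.
#'
#' @param graph An `interaction_graph`.
#' @param decomposition A `level_decomposition` computed on `graph`.
#' @return A list with `nodes` (all symbols) and `edges` (the full edge
#'   tibble).
#' @export
whole_graph <- function(graph, decomposition) {
  stopifnot(inherits(decomposition, "level_decomposition"))
  if (!setequal(decomposition$level_of$symbol, graph_symbols(graph))) {
    abort("decomposition was not computed on this graph")
  }
  list(nodes = graph_symbols(graph), edges = graph_edges(graph))
}

#' Write level assignments onto the graph's node table
#'
#' @param graph An `interaction_graph`.
#' @param decomposition A `level_decomposition` computed on `graph`.
#' @return The graph with its nodes' `level` column filled in (`NA` =
#'   whole-graph only); queries with a level cap need this.
#' @export
set_levels <- function(graph, decomposition) {
  stopifnot(inherits(decomposition, "level_decomposition"))
  lo <- decomposition$level_of
  idx <- match(graph$nodes$symbol, lo$symbol)
  if (anyNA(idx)) abort("decomposition does not cover all graph nodes")
  graph$nodes$level <- lo$level[idx]
  graph
}

#' @export
print.level_decomposition <- function(x, ...) {
  cat(sprintf(
    "<level_decomposition> saturation at level %s; %d/%d nodes levelled\n",
    ifelse(is.na(x$saturation_level), "(not reached)", x$saturation_level),
    sum(!is.na(x$level_of$level)), nrow(x$level_of)))
  print(as.data.frame(x$per_level), row.names = FALSE)
  if (length(x$unconnected_drivers) > 0) {
    cat("  unconnected drivers:",
        paste(x$unconnected_drivers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a level decomposition into the per-node level table
#'
#' @param x A `level_decomposition`.
#' @param ... Unused.
#' @method tidy level_decomposition
#' @export
tidy.level_decomposition <- function(x, ...) x$level_of

#' One-row summary of a level decomposition
#'
#' @param x A `level_decomposition`.
#' @param ... Unused.
#' @method glance level_decomposition
#' @export
glance.level_decomposition <- function(x, ...) {
  sat <- x$per_level[nrow(x$per_level), ]
  tibble(
    saturation_level = x$saturation_level,
    n_levels = nrow(x$per_level),
    levelled_nodes = sat$total_nodes,
    levelled_edges = sat$total_edges,
    whole_nodes = x$whole$total_nodes,
    whole_edges = x$whole$total_edges,
    n_unconnected_drivers = length(x$unconnected_drivers)
  )
}

#' Export level tables as TSV
#'
#' `write_level_table()` writes one row per node (`symbol`, `level` with
#' `"whole"` for unlevelled nodes, `is_driver`, `driver_class`);
#' `write_level_summary()` writes the per-level growth table (`level`,
#' `new_nodes`, `new_edges`, `total_nodes`, `total_edges`).
#'
#' @param decomposition A `level_decomposition`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_level_table <- function(decomposition, path) {
  lo <- decomposition$level_of
  lo$level <- level_label(lo$level)
  readr::write_tsv(lo, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_level_table
#' @export
write_level_summary <- function(decomposition, path) {
  readr::write_tsv(decomposition$per_level, path, progress = FALSE)
  invisible(path)
}
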