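#' Build the directed evidence multigraph
#'
#' Nodes are all edge endpoints plus all driver genes; drivers with no
#' interaction become isolated nodes so their disconnection is visible
#' rather than silently lost. Duplicate `(src, dst, itype)` edges are
#' merged with their evidence concatenated, so the same pair may still
#' carry parallel physical and genetic edges.
#'
#' @param edges A directed-interaction table (see [interaction_tbl()]).
#' @param drivers Driver genes: either a tibble with columns `symbol` and
#'   `driver_class` (`"syndromic"`, `"non_syndromic"` or `"both"`), or a
#'   character vector (then classed `"non_syndromic"`). May be `NULL`.
#' @param alias_table Optional [alias_table()]; when given, driver symbols
#'   must resolve to a canonical symbol — a driver that fails to resolve is
#'   a fatal error, since the skeleton would silently lose a seed.
#' @param extra_symbols Optional character vector of additional node
#'   symbols (e.g. genes known to the nomenclature but with no recorded
#'   interaction); they become isolated nodes.
#' @return An object of class `interaction_graph`: a list with tibbles
#'   `nodes` (`symbol`, `is_driver`, `driver_class`, `level`,
#'   `variant_count`, plus one column per attached annotation layer) and
#'   `edges` (`src`, `dst`, `itype`, `evidence`).
#' @export
build_graph <- function(edges, drivers = NULL, alias_table = NULL,
                        extra_symbols = NULL) {
  edges <- as_tibble(edges)
  drivers <- normalize_drivers(drivers)
  if (!is.null(alias_table) && nrow(drivers) > 0) {
    res <- resolve_symbol(drivers$symbol, alias_table)
    if (anyNA(res)) {
      abort(paste0("driver symbol(s) not resolvable to an official symbol: ",
                   paste(drivers$symbol[is.na(res)], collapse = ", ")))
    }
    drivers$symbol <- res
    drivers <- drivers[!duplicated(drivers$symbol), , drop = FALSE]
  }
  if (any(!nzchar(drivers$symbol))) abort("empty driver symbol")
  edges <- merge_interactions(edges)
  symbols <- unique(c(edges$src, edges$dst, drivers$symbol, extra_symbols))
  cls <- setNames(drivers$driver_class, drivers$symbol)
  nodes <- tibble(
    symbol = symbols,
    is_driver = symbols %in% drivers$symbol,
    driver_class = unname(ifelse(symbols %in% drivers$symbol,
                                 cls[symbols], "none")),
    level = NA_integer_,
    variant_count = NA_integer_
  )
  new_interaction_graph(nodes, edges)
}

normalize_drivers <- function(drivers) {
  if (is.null(drivers)) {
    return(tibble(symbol = character(), driver_class = character()))
  }
  if (is.character(drivers)) {
    return(tibble(symbol = unique(drivers), driver_class = "non_syndromic"))
  }
  drivers <- as_tibble(drivers)
  stopifnot(all(c("symbol", "driver_class") %in% names(drivers)))
  bad <- setdiff(unique(drivers$driver_class),
                 setdiff(DRIVER_CLASSES, "none"))
  if (length(bad) > 0) {
    abort(paste0("unknown driver class: ", paste(bad, collapse = ", ")))
  }
  drivers[!duplicated(drivers$symbol), c("symbol", "driver_class")]
}

new_interaction_graph <- function(nodes, edges, layers = NULL,
                                  active_layer = NULL) {
  missing <- setdiff(unique(c(edges$src, edges$dst)), nodes$symbol)
  if (length(missing) > 0) {
    abort(paste0("edge endpoint(s) missing from node table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  structure(list(nodes = nodes, edges = edges),
            layers = layers %||% list(),
            active_layer = active_layer,
            class = "interaction_graph")
}

#' Graph component accessors
#'
#' @param graph An `interaction_graph`.
#' @return `graph_nodes()` and `graph_edges()` return the node and edge
#'   tibbles; `graph_symbols()` the node symbols; `driver_symbols()` the
#'   driver subset.
#' @export
graph_nodes <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  graph$nodes
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  graph$edges
}

#' @rdname graph_nodes
#' @export
graph_symbols <- function(graph) graph_nodes(graph)$symbol

#' @rdname graph_nodes
#' @export
driver_symbols <- function(graph) {
  n <- graph_nodes(graph)
  n$symbol[n$is_driver]
}

check_symbols <- function(graph, symbols) {
  missing <- setdiff(symbols, graph_symbols(graph))
  if (length(missing) > 0) {
    abort(paste0("unknown gene symbol(s): ", paste(missing, collapse = ", ")))
  }
  invisible(symbols)
}

# out-/in-adjacency as named lists of sorted unique neighbor vectors;
# symbols with no neighbors are present with character(0)
adjacency_index <- function(graph) {
  syms <- graph_symbols(graph)
  edges <- graph_edges(graph)
  empty <- setNames(rep(list(character()), length(syms)), syms)
  out <- empty
  if (nrow(edges) > 0) {
    sp <- split(edges$dst, edges$src)
    out[names(sp)] <- lapply(sp, function(v) sort(unique(v), method = "radix"))
  }
  inn <- empty
  if (nrow(edges) > 0) {
    sp <- split(edges$src, edges$dst)
    inn[names(sp)] <- lapply(sp, function(v) sort(unique(v), method = "radix"))
  }
  list(out = out, `in` = inn)
}

#' Parents, children or both of a node
#'
#' Under directed interactions, parents are in-neighbors and children are
#' out-neighbors; a self-loop makes a node its own neighbor.
#'
#' @param graph An `interaction_graph`.
#' @param symbol A node symbol.
#' @param direction `"both"` (default), `"parents"` or `"children"`.
#' @return A sorted character vector of neighbor symbols.
#' @export
node_neighbors <- function(graph, symbol,
                           direction = c("both", "parents", "children")) {
  direction <- match.arg(direction)
  check_symbols(graph, symbol)
  adj <- adjacency_index(graph)
  res <- switch(direction,
    parents = adj$`in`[[symbol]],
    children = adj$out[[symbol]],
    both = union(adj$`in`[[symbol]], adj$out[[symbol]])
  )
  sort(res, method = "radix")
}

#' Induced subgraph over a set of symbols
#'
#' Keeps the given nodes and every edge with both endpoints among them,
#' preserving driver status, levels and annotation layers.
#'
#' @param graph An `interaction_graph`.
#' @param symbols Character vector of node symbols to keep.
#' @return An `interaction_graph`.
#' @export
graph_subset <- function(graph, symbols) {
  check_symbols(graph, symbols)
  nodes <- graph_nodes(graph)
  edges <- graph_edges(graph)
  nodes <- nodes[nodes$symbol %in% symbols, , drop = FALSE]
  edges <- edges[edges$src %in% symbols & edges$dst %in% symbols, ,
                 drop = FALSE]
  new_interaction_graph(nodes, edges, layers = attr(graph, "layers"),
                        active_layer = attr(graph, "active_layer"))
}

#' Convert to an igraph object
#'
#' Edge attributes: `itype`, `n_evidences`, `sources` (semicolon-joined
#' evidence databases); vertex attributes: `is_driver`, `driver_class`,
#' `level` (`"whole"` for nodes outside every expansion level).
#'
#' @param graph An `interaction_graph`.
#' @return An [igraph::graph] (directed, possibly with parallel edges and
#'   self-loops).
#' @export
as_igraph <- function(graph) {
  nodes <- graph_nodes(graph)
  edges <- graph_edges(graph)
  v <- data.frame(name = nodes$symbol, is_driver = nodes$is_driver,
                  driver_class = nodes$driver_class,
                  level = level_label(nodes$level),
                  stringsAsFactors = FALSE)
  e <- data.frame(from = edges$src, to = edges$dst, itype = edges$itype,
                  n_evidences = n_evidences(edges),
                  sources = map_chr(edges$evidence, function(ev) {
                    paste(sort(unique(ev$source_db)), collapse = ";")
                  }),
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

level_label <- function(level) ifelse(is.na(level), "whole",
                                      as.character(level))

#' @export
print.interaction_graph <- function(x, ...) {
  nd <- graph_nodes(x)
  ed <- graph_edges(x)
  cat(sprintf(
    "<interaction_graph> %d nodes (%d drivers), %d directed edges\n",
    nrow(nd), sum(nd$is_driver), nrow(ed)))
  if (nrow(ed) > 0) {
    tab <- table(ed$itype)
    cat("  edge types:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  layers <- names(attr(x, "layers"))
  if (length(layers) > 0) {
    cat("  annotation layers:", paste(layers, collapse = ", "), "\n")
  }
  if (any(!is.na(nd$level))) {
    cat(sprintf("  levelled: %d node(s) in levels 0..%d, %d in whole graph\n",
                sum(!is.na(nd$level)), max(nd$level, na.rm = TRUE),
                sum(is.na(nd$level))))
  }
  invisible(x)
}

#' Tidy an interaction graph into its edge table
#'
#' One row per directed typed edge with evidence counts and source
#' databases; the `evidence` list-column is summarised away.
#'
#' @param x An `interaction_graph`.
#' @param ... Unused.
#' @return A tibble with columns `src`, `dst`, `itype`, `n_evidences`,
#'   `sources`.
#' @method tidy interaction_graph
#' @export
tidy.interaction_graph <- function(x, ...) {
  edges <- graph_edges(x)
  tibble(
    src = edges$src, dst = edges$dst, itype = edges$itype,
    n_evidences = n_evidences(edges),
    sources = map_chr(edges$evidence, function(ev) {
      paste(sort(unique(ev$source_db)), collapse = ";")
    })
  )
}

#' One-row summary of an interaction graph
#'
#' @param x An `interaction_graph`.
#' @param ... Unused.
#' @return The [compute_stats()] row for the full graph.
#' @method glance interaction_graph
#' @export
glance.interaction_graph <- function(x, ...) compute_stats(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
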