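# BFS distances from `src` over an out-adjacency list, optionally
# restricted to `allowed` symbols; returns named integer vector (NA =
# unreachable). `src` itself gets distance 0.
bfs_distances <- function(adj_out, src, allowed = NULL) {
  syms <- names(adj_out)
  dist <- setNames(rep(NA_integer_, length(syms)), syms)
  if (!is.null(allowed) && !(src %in% allowed)) return(dist)
  dist[[src]] <- 0L
  frontier <- src
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(unlist(adj_out[frontier], use.names = FALSE))
    if (!is.null(allowed)) nxt <- nxt[nxt %in% allowed]
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# enumerate every node sequence of a shortest path ending at `dst`, by
# backtracking through in-neighbors one BFS layer up; `dist` comes from
# bfs_distances. Returns list of character vectors (src ... dst), complete
# and lexicographically sorted; capped at max_paths (attr "truncated").
backtrack_paths <- function(adj_in, dist, dst, allowed = NULL,
                            max_paths = Inf) {
  truncated <- FALSE
  walk <- function(v) {
    if (dist[[v]] == 0L) return(list(v))
    preds <- adj_in[[v]]
    if (!is.null(allowed)) preds <- preds[preds %in% allowed]
    preds <- preds[!is.na(dist[preds]) & dist[preds] == dist[[v]] - 1L]
    out <- list()
    for (p in preds) {
      for (pre in walk(p)) out[[length(out) + 1L]] <- c(pre, v)
    }
    out
  }
  paths <- walk(dst)
  keys <- map_chr(paths, paste, collapse = "\r")
  paths <- paths[order(keys, method = "radix")]
  if (length(paths) > max_paths) {
    paths <- paths[seq_len(max_paths)]
    truncated <- TRUE
  }
  structure(paths, truncated = truncated)
}

# interaction types present on each step of a node sequence
step_edge_types <- function(edges, nodes_seq) {
  if (length(nodes_seq) < 2) return(list())
  map(seq_len(length(nodes_seq) - 1L), function(i) {
    sort(unique(edges$itype[edges$src == nodes_seq[i] &
                              edges$dst == nodes_seq[i + 1L]]))
  })
}

# wrap a list of node sequences as a path-result tibble
path_tibble <- function(paths, graph, truncated = FALSE) {
  edges <- graph_edges(graph)
  out <- tibble(
    path = map_chr(paths, paste, collapse = " -> "),
    nodes = paths,
    n_edges = map_int(paths, function(p) length(p) - 1L),
    edge_types = map(paths, function(p) step_edge_types(edges, p))
  )
  attr(out, "truncated") <- truncated
  class(out) <- c("path_tbl", class(out))
  out
}

#' All shortest directed paths between two genes
#'
#' Unweighted breadth-first search from `src`, then exhaustive backtracking
#' through the predecessor layers, so the result is the complete set of
#' minimal-length directed node sequences from `src` to `dst`. Paths are
#' node sequences: parallel edges of different types between consecutive
#' nodes do not multiply paths — the types present at each step are listed
#' in the `edge_types` column instead. Results are sorted
#' lexicographically by node symbols, which makes output deterministic.
#'
#' When `src == dst` the single zero-length path `[src]` is returned; an
#' unreachable `dst` yields an empty table.
#'
#' @param graph An `interaction_graph`.
#' @param src,dst Gene symbols present in the graph.
#' @param allowed Optional character vector restricting the search to a
#'   node subset; must contain `src` and `dst`.
#' @param max_paths Cap on the number of returned paths (the complete set
#'   can grow combinatorially on dense graphs); when hit, the result
#'   carries attribute `truncated = TRUE`.
#' @return A `path_tbl` tibble: `path` (printable string), `nodes`
#'   (list-column of symbol vectors), `n_edges`, `edge_types`.
#' @export
all_shortest_paths <- function(graph, src, dst, allowed = NULL,
                               max_paths = Inf) {
  check_symbols(graph, c(src, dst))
  if (!is.null(allowed)) {
    if (!all(c(src, dst) %in% allowed)) {
      abort("`allowed` must contain both query genes")
    }
  }
  if (src == dst) return(path_tibble(list(src), graph))
  adj <- adjacency_index(graph)
  dist <- bfs_distances(adj$out, src, allowed)
  if (is.na(dist[[dst]])) return(path_tibble(list(), graph))
  paths <- backtrack_paths(adj$`in`, dist, dst, allowed, max_paths)
  trunc <- isTRUE(attr(paths, "truncated"))
  attr(paths, "truncated") <- NULL
  path_tibble(paths, graph, truncated = trunc)
}

#' @export
print.path_tbl <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<path_tbl> no paths\n")
    return(invisible(x))
  }
  cat(sprintf("<path_tbl> %d shortest path(s) of %d edge(s)%s\n",
              nrow(x), x$n_edges[1],
              if (isTRUE(attr(x, "truncated"))) " [truncated]" else ""))
  lab <- if ("direction" %in% names(x)) paste0("  [", x$direction, "]") else
    rep("", nrow(x))
  for (i in head(seq_len(nrow(x)), 20)) cat(" ", x$path[i], lab[i], "\n")
  if (nrow(x) > 20) cat(sprintf("  ... and %d more\n", nrow(x) - 20L))
  invisible(x)
}
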