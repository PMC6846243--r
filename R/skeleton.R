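#' Reduce a graph to its driver-gene skeleton
#'
#' The skeleton is the union, over every ordered pair of distinct driver
#' genes `(a, b)`, of all minimal-length directed paths from `a` to `b`.
#' Its node set is every node lying on at least one such path; its edge set
#' is every graph edge (all parallel types included) joining two
#' consecutive nodes of such a path. Unreachable pairs contribute nothing.
#' Drivers that can reach, or be reached from, no other driver are excluded
#' from the skeleton and reported as unconnected.
#'
#' Membership is decided per ordered pair with the standard distance
#' criterion: with `dF` the BFS distance from `a` and `dB` the distance to
#' `b` (BFS on the reversed graph), node `v` is on a shortest `a -> b` path
#' iff `dF(v) + dB(v) == dF(b)`, and edge `u -> v` iff
#' `dF(u) + 1 + dB(v) == dF(b)`. This avoids enumerating the (possibly
#' combinatorial) path set while giving exactly its union.
#'
#' @param graph An `interaction_graph`.
#' @param drivers Optional character vector of driver symbols; defaults to
#'   the graph's driver set. At least two are required.
#' @return An object of class `skeleton_result`: list with `nodes` (sorted
#'   symbols), `edges` (directed-interaction tibble), `drivers`,
#'   `unconnected_drivers`, and `driver_distances` (the ordered-pair
#'   distance tibble).
#' @export
build_skeleton <- function(graph, drivers = NULL) {
  drivers <- drivers %||% driver_symbols(graph)
  check_symbols(graph, drivers)
  drivers <- unique(drivers)
  if (length(drivers) < 2) {
    abort("skeleton construction needs at least 2 driver genes")
  }
  adj <- adjacency_index(graph)
  rev_adj <- adj$`in`
  fwd <- lapply(setNames(drivers, drivers),
                function(a) bfs_distances(adj$out, a))
  bwd <- lapply(setNames(drivers, drivers),
                function(b) bfs_distances(rev_adj, b))

  edges <- graph_edges(graph)
  syms <- graph_symbols(graph)
  in_nodes <- setNames(rep(FALSE, length(syms)), syms)
  in_edge <- rep(FALSE, nrow(edges))
  dists <- list()
  for (a in drivers) {
    for (b in setdiff(drivers, a)) {
      d <- fwd[[a]][[b]]
      dists[[length(dists) + 1L]] <- tibble(from = a, to = b, distance = d)
      if (is.na(d)) next
      on_path <- !is.na(fwd[[a]]) & !is.na(bwd[[b]]) &
        fwd[[a]] + bwd[[b]] == d
      in_nodes <- in_nodes | on_path
      if (nrow(edges) > 0) {
        du <- fwd[[a]][edges$src]
        dv <- bwd[[b]][edges$dst]
        in_edge <- in_edge | (!is.na(du) & !is.na(dv) & du + 1L + dv == d)
      }
    }
  }
  pair_dist <- bind_rows(dists)
  connected <- map_chr(drivers, function(d) {
    reach <- pair_dist[pair_dist$from == d | pair_dist$to == d, ]
    if (any(!is.na(reach$distance))) d else NA_character_
  })
  unconnected <- drivers[is.na(connected)]
  structure(
    list(
      nodes = sort(names(in_nodes)[in_nodes], method = "radix"),
      edges = edges[in_edge, , drop = FALSE],
      drivers = drivers,
      unconnected_drivers = sort(unconnected, method = "radix"),
      driver_distances = pair_dist
    ),
    class = "skeleton_result"
  )
}

#' @export
print.skeleton_result <- function(x, ...) {
  cat(sprintf(
    "<skeleton_result> %d nodes, %d edges from %d drivers (%d unconnected)\n",
    length(x$nodes), nrow(x$edges), length(x$drivers),
    length(x$unconnected_drivers)))
  invisible(x)
}

#' @rdname build_skeleton
#' @param x A `skeleton_result`.
#' @param ... Unused.
#' @method tidy skeleton_result
#' @export
tidy.skeleton_result <- function(x, ...) x$driver_distances

#' @rdname build_skeleton
#' @method glance skeleton_result
#' @export
glance.skeleton_result <- function(x, ...) {
  finite <- x$driver_distances$distance
  dmax <- suppressWarnings(max(finite, na.rm = TRUE))
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_drivers = length(x$drivers),
    n_unconnected_drivers = length(x$unconnected_drivers),
    median_driver_distance = stats::median(finite, na.rm = TRUE),
    max_driver_distance = if (is.finite(dmax)) as.integer(dmax) else
      NA_integer_
  )
}
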