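# Independent brute-force oracles. These deliberately share no code with
# the package: shortest paths are found by depth-first enumeration of
# simple paths with branch-and-bound pruning, and the skeleton by a
# literal union over ordered driver pairs.

oracle_shortest_paths <- function(edges, src, dst, allowed = NULL) {
  if (src == dst) return(list(src))
  if (!is.null(allowed)) {
    edges <- edges[edges$src %in% allowed & edges$dst %in% allowed, ,
                   drop = FALSE]
  }
  adj <- lapply(split(edges$dst, edges$src), unique)
  best <- Inf
  found <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == dst) {
      len <- length(path) - 1L
      if (len < best) {
        best <<- len
        found <<- list(path)
      } else if (len == best) {
        found[[length(found) + 1L]] <<- path
      }
      return(invisible())
    }
    if (length(path) - 1L >= best) return(invisible())
    for (w in adj[[v]]) if (!(w %in% path)) rec(c(path, w))
  }
  rec(src)
  found[order(vapply(found, paste, "", collapse = "\r"), method = "radix")]
}

# union of all minimal-length simple paths over every ordered driver pair
oracle_skeleton <- function(edges, drivers) {
  nodes <- character()
  edge_keys <- character()
  connected <- character()
  for (a in drivers) {
    for (b in setdiff(drivers, a)) {
      paths <- oracle_shortest_paths(edges, a, b)
      if (length(paths) == 0) next
      connected <- union(connected, c(a, b))
      for (p in paths) {
        nodes <- union(nodes, p)
        edge_keys <- union(edge_keys, paste(p[-length(p)], p[-1], sep = "->"))
      }
    }
  }
  on_edge <- paste(edges$src, edges$dst, sep = "->") %in% edge_keys
  list(nodes = sort(nodes, method = "radix"),
       edges = edges[on_edge, , drop = FALSE],
       unconnected = sort(setdiff(drivers, connected), method = "radix"))
}

# random sparse digraph fixture for oracle comparisons
rand_digraph <- function(seed, n_max = 12, p = NULL) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  p <- p %||% (2 / n)
  syms <- paste0("N", sprintf("%02d", seq_len(n)))
  grid <- expand.grid(src = syms, dst = syms, stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < p
  edges <- grid[keep, , drop = FALSE]
  edges$itype <- sample(c("physical", "genetic", "unknown"), nrow(edges),
                        replace = TRUE, prob = c(0.6, 0.25, 0.15))
  edges <- edges[!duplicated(edges[, c("src", "dst", "itype")]), ,
                 drop = FALSE]
  drivers <- sample(syms, sample(2:min(5, n), 1))
  list(symbols = syms, edges = tibble::as_tibble(edges), drivers = drivers)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

rand_graph_obj <- function(rd) {
  ev <- evidence_tbl("biogrid", "two hybrid")
  edges <- interaction_tbl(rd$edges$src, rd$edges$dst, rd$edges$itype,
                           lapply(seq_len(nrow(rd$edges)), function(i) ev))
  build_graph(edges, rd$drivers, extra_symbols = rd$symbols)
}
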