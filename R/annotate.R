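#' Attach a numeric annotation layer to the graph's nodes
#'
#' Annotation layers project per-gene numbers — expression summaries,
#' fold changes, variant counts — onto the network without touching its
#' topology. Layers are generic named-numeric maps; any number may
#' coexist, and which one is "active" (e.g. for plotting) is pure
#' metadata. Attaching the same layer twice is idempotent.
#'
#' @param graph An `interaction_graph`.
#' @param name Layer name (e.g. `"retina_absolute"`); becomes a node
#'   column.
#' @param values Named numeric vector (names = symbols) or a two-column
#'   data frame (`symbol`, `value`). All values must be finite.
#' @param default Value for nodes absent from `values` (default 0).
#' @return The graph with the layer attached.
#' @export
attach_layer <- function(graph, name, values, default = 0) {
  stopifnot(inherits(graph, "interaction_graph"), nzchar(name))
  if (is.data.frame(values)) {
    values <- setNames(as.numeric(values[[2]]), as.character(values[[1]]))
  }
  if (!is.numeric(values) || is.null(names(values))) {
    abort("`values` must be a named numeric vector or a symbol/value table")
  }
  bad <- names(values)[!is.finite(values)]
  if (length(bad) > 0) {
    abort(paste0("non-finite annotation value for: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.finite(default)) abort("`default` must be finite")
  col <- unname(values[graph$nodes$symbol])
  col[is.na(col)] <- default
  graph$nodes[[name]] <- col
  layers <- attr(graph, "layers")
  layers[[name]] <- list(default = default)
  attr(graph, "layers") <- layers
  if (is.null(attr(graph, "active_layer"))) {
    attr(graph, "active_layer") <- name
  }
  graph
}

#' @rdname attach_layer
#' @export
layer_names <- function(graph) names(attr(graph, "layers"))

#' @rdname attach_layer
#' @details `set_active_layer()` switches the active layer; metadata only,
#'   the node table is untouched.
#' @export
set_active_layer <- function(graph, name) {
  if (!(name %in% layer_names(graph))) {
    abort(paste0("no such annotation layer: ", name))
  }
  attr(graph, "active_layer") <- name
  graph
}

#' @rdname attach_layer
#' @export
active_layer <- function(graph) attr(graph, "active_layer")

#' Set per-gene known-variant counts
#'
#' @param graph An `interaction_graph`.
#' @param counts Named integer vector or `symbol`/`count` table;
#'   non-negative.
#' @return The graph with `variant_count` filled in.
#' @export
set_variant_counts <- function(graph, counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(as.integer(counts[[2]]), as.character(counts[[1]]))
  }
  if (any(counts < 0, na.rm = TRUE)) abort("variant counts must be >= 0")
  idx <- match(graph$nodes$symbol, names(counts))
  hit <- !is.na(idx)
  graph$nodes$variant_count[hit] <- as.integer(counts[idx[hit]])
  graph
}

# stable fingerprint of topology (node set + typed edge multiset); used to
# assert that annotation and export are topology-pure
topology_hash <- function(graph) {
  nodes <- sort(graph_symbols(graph), method = "radix")
  edges <- graph_edges(graph)
  ek <- sort(paste(edges$src, edges$dst, edges$itype, sep = "\r"),
             method = "radix")
  paste(length(nodes), paste(nodes, collapse = "|"),
        paste(ek, collapse = "|"), sep = "\n")
}
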