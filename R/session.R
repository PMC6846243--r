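SESSION_FORMAT_VERSION <- 1L

#' Save a working session with exact layout positions
#'
#' A session freezes a (sub)graph together with the researcher's manual
#' layout: node records carry symbol, level, driver class, annotations and
#' an `(x, y)` position; edge records carry the full supporting evidence.
#' Positions are serialized at 17 significant digits so that reloading
#' reproduces every coordinate bit-exactly and the network is laid out
#' exactly as it was left.
#'
#' @param graph An `interaction_graph`.
#' @param positions A data frame `symbol`, `x`, `y` covering every node of
#'   `graph` with finite coordinates; a missing node is an error naming it.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_session <- function(graph, positions, path) {
  stopifnot(inherits(graph, "interaction_graph"))
  positions <- as_tibble(positions)
  stopifnot(all(c("symbol", "x", "y") %in% names(positions)))
  nodes <- graph_nodes(graph)
  missing <- setdiff(nodes$symbol, positions$symbol)
  if (length(missing) > 0) {
    abort(paste0("no position for node(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(positions$x)) || any(!is.finite(positions$y))) {
    abort("positions must be finite")
  }
  idx <- match(nodes$symbol, positions$symbol)
  layers <- layer_names(graph)
  node_elems <- map(seq_len(nrow(nodes)), function(i) {
    ann <- if (length(layers) > 0) {
      as.list(setNames(map_dbl(layers, function(l) nodes[[l]][i]), layers))
    } else {
      stats::setNames(list(), character())
    }
    list(symbol = nodes$symbol[i],
         level = level_label(nodes$level[i]),
         driver_class = nodes$driver_class[i],
         variant_count = nodes$variant_count[i],
         annotations = ann,
         position = list(x = positions$x[idx[i]], y = positions$y[idx[i]]))
  })
  edges <- graph_edges(graph)
  edge_elems <- map(seq_len(nrow(edges)), function(i) {
    ev <- edges$evidence[[i]]
    list(src = edges$src[i], dst = edges$dst[i], itype = edges$itype[i],
         evidence = map(seq_len(nrow(ev)), function(j) {
           list(source_db = ev$source_db[j], detail = ev$detail[j],
                reference = ev$reference[j], score = ev$score[j])
         }))
  })
  doc <- list(
    format_version = SESSION_FORMAT_VERSION,
    metadata = list(
      tool = "skelnet",
      tool_version = as.character(utils::packageVersion("skelnet")),
      active_layer = active_layer(graph),
      layer_defaults = lapply(attr(graph, "layers"), `[[`, "default")
    ),
    elements = list(nodes = node_elems, edges = edge_elems)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Restore a saved session
#'
#' Sessions from older minor versions of the format load with defaults for
#' any fields they lack; a file that is not a session errors with context.
#'
#' @param path Path to a session JSON written by [save_session()].
#' @return A list of class `skelnet_session`: `graph` (an
#'   `interaction_graph`), `positions` (tibble `symbol`, `x`, `y`) and
#'   `metadata`.
#' @export
load_session <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) abort(paste0("malformed session file ", path, ": ",
                                     conditionMessage(e))))
  if (is.null(doc$format_version) || is.null(doc$elements)) {
    abort(paste0(path, ": not a session file (missing format_version/elements)"))
  }
  ns <- doc$elements$nodes %||% list()
  nodes <- tibble(
    symbol = map_chr(ns, "symbol"),
    is_driver = map_chr(ns, function(n) n$driver_class %||% "none") != "none",
    driver_class = map_chr(ns, function(n) n$driver_class %||% "none"),
    level = map_int(ns, function(n) {
      l <- n$level %||% "whole"
      if (identical(l, "whole")) NA_integer_ else as.integer(l)
    }),
    variant_count = map_int(ns, function(n) {
      v <- n$variant_count
      if (is.null(v)) NA_integer_ else as.integer(v)
    })
  )
  layer_names <- unique(unlist(map(ns, function(n) names(n$annotations))))
  for (l in layer_names) {
    nodes[[l]] <- map_dbl(ns, function(n) {
      v <- n$annotations[[l]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    })
  }
  es <- doc$elements$edges %||% list()
  edges <- interaction_tbl(
    src = map_chr(es, "src"),
    dst = map_chr(es, "dst"),
    itype = map_chr(es, "itype"),
    evidence = map(es, function(e) {
      ev <- e$evidence %||% list()
      evidence_tbl(
        source_db = map_chr(ev, function(x) x$source_db %||% "session"),
        detail = map_chr(ev, function(x) x$detail %||% ""),
        reference = map_chr(ev, function(x) x$reference %||% NA_character_),
        score = map_dbl(ev, function(x) {
          if (is.null(x$score)) NA_real_ else as.numeric(x$score)
        }))
    })
  )
  defaults <- doc$metadata$layer_defaults %||% list()
  layers <- setNames(
    map(layer_names, function(l) list(default = defaults[[l]] %||% 0)),
    layer_names)
  graph <- new_interaction_graph(
    nodes, edges, layers = layers,
    active_layer = doc$metadata$active_layer)
  positions <- tibble(
    symbol = map_chr(ns, "symbol"),
    x = map_dbl(ns, function(n) as.numeric(n$position$x)),
    y = map_dbl(ns, function(n) as.numeric(n$position$y))
  )
  structure(list(graph = graph, positions = positions,
                 metadata = doc$metadata),
            class = "skelnet_session")
}

#' @export
print.skelnet_session <- function(x, ...) {
  cat(sprintf("<skelnet_session> %d nodes, %d edges (format v%s)\n",
              nrow(graph_nodes(x$graph)), nrow(graph_edges(x$graph)),
              x$metadata$tool_version %||% "?"))
  invisible(x)
}
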