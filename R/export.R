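#' Export a graph as Cytoscape.js elements JSON
#'
#' Emits the standard Cytoscape.js `elements` structure: node elements with
#' `data` (`id`, `level`, `driver_class`, `is_driver`, `annotations`) and
#' optional `position` (`x`, `y`); edge elements with `data` (`id`,
#' `source`, `target`, `itype`, `n_evidences`, `sources`). Parallel edges
#' of different types become separate edge elements. Export never alters
#' the graph.
#'
#' @param graph An `interaction_graph`.
#' @param positions Optional `symbol`/`x`/`y` data frame; nodes without a
#'   position get no `position` entry.
#' @param path Optional output file; when given the document is written as
#'   JSON (positions at full precision).
#' @return The elements structure as a list, invisibly when `path` is
#'   given.
#' @export
export_cytoscape_json <- function(graph, positions = NULL, path = NULL) {
  nodes <- graph_nodes(graph)
  edges <- graph_edges(graph)
  layers <- layer_names(graph)
  if (!is.null(positions)) positions <- as_tibble(positions)
  node_elems <- map(seq_len(nrow(nodes)), function(i) {
    ann <- if (length(layers) > 0) {
      as.list(setNames(map_dbl(layers, function(l) nodes[[l]][i]), layers))
    } else {
      stats::setNames(list(), character())
    }
    el <- list(data = list(
      id = nodes$symbol[i],
      level = level_label(nodes$level[i]),
      driver_class = nodes$driver_class[i],
      is_driver = nodes$is_driver[i],
      annotations = ann))
    if (!is.null(positions)) {
      j <- match(nodes$symbol[i], positions$symbol)
      if (!is.na(j)) {
        el$position <- list(x = positions$x[j], y = positions$y[j])
      }
    }
    el
  })
  nev <- n_evidences(edges)
  edge_elems <- map(seq_len(nrow(edges)), function(i) {
    list(data = list(
      id = paste0(edges$src[i], "->", edges$dst[i], "#", edges$itype[i]),
      source = edges$src[i],
      target = edges$dst[i],
      itype = edges$itype[i],
      n_evidences = nev[i],
      sources = paste(sort(unique(edges$evidence[[i]]$source_db)),
                      collapse = ";")))
  })
  doc <- list(elements = list(nodes = node_elems, edges = edge_elems))
  validate_cytoscape_elements(doc)
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE)
    return(invisible(doc))
  }
  doc
}

# structural schema check for the Cytoscape.js elements document
validate_cytoscape_elements <- function(doc) {
  if (!is.list(doc$elements) ||
      !all(c("nodes", "edges") %in% names(doc$elements))) {
    abort("cytoscape document must have elements$nodes and elements$edges")
  }
  ids <- map_chr(doc$elements$nodes, function(n) {
    if (is.null(n$data$id)) abort("cytoscape node element without data$id")
    n$data$id
  })
  if (anyDuplicated(ids)) abort("duplicate cytoscape node ids")
  for (e in doc$elements$edges) {
    d <- e$data
    if (is.null(d$source) || is.null(d$target) || is.null(d$itype)) {
      abort("cytoscape edge element missing source/target/itype")
    }
    if (!(d$source %in% ids) || !(d$target %in% ids)) {
      abort(paste0("cytoscape edge references unknown node: ",
                   d$source, " -> ", d$target))
    }
  }
  invisible(doc)
}

#' Import a Cytoscape.js elements document back into a graph
#'
#' The inverse of [export_cytoscape_json()] at the topology level: node and
#' edge identities, levels, driver classes, annotations and positions are
#' recovered; per-evidence detail is summarised in the export and comes
#' back as one evidence record per source database.
#'
#' @param x A path to a JSON file, or the elements list itself.
#' @return A list `graph` (an `interaction_graph`) and `positions`
#'   (tibble; zero rows when the export carried no positions).
#' @export
import_cytoscape_json <- function(x) {
  doc <- if (is.character(x)) jsonlite::read_json(x) else x
  validate_cytoscape_elements(doc)
  ns <- doc$elements$nodes
  nodes <- tibble(
    symbol = map_chr(ns, function(n) n$data$id),
    is_driver = map_chr(ns, function(n) n$data$driver_class %||% "none") !=
      "none",
    driver_class = map_chr(ns, function(n) n$data$driver_class %||% "none"),
    level = map_int(ns, function(n) {
      l <- n$data$level %||% "whole"
      if (identical(l, "whole")) NA_integer_ else as.integer(l)
    }),
    variant_count = NA_integer_
  )
  layer_names <- unique(unlist(map(ns, function(n) names(n$data$annotations))))
  for (l in layer_names) {
    nodes[[l]] <- map_dbl(ns, function(n) {
      v <- n$data$annotations[[l]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    })
  }
  es <- doc$elements$edges
  edges <- interaction_tbl(
    src = map_chr(es, function(e) e$data$source),
    dst = map_chr(es, function(e) e$data$target),
    itype = map_chr(es, function(e) e$data$itype),
    evidence = map(es, function(e) {
      srcs <- strsplit(e$data$sources %||% "session", ";")[[1]]
      evidence_tbl(srcs, "imported summary")
    })
  )
  layers <- setNames(map(layer_names, function(l) list(default = 0)),
                     layer_names)
  graph <- new_interaction_graph(nodes, edges, layers = layers)
  has_pos <- map(ns, function(n) n$position)
  keep <- !vapply(has_pos, is.null, logical(1))
  positions <- tibble(
    symbol = nodes$symbol[keep],
    x = map_dbl(ns[keep], function(n) as.numeric(n$position$x)),
    y = map_dbl(ns[keep], function(n) as.numeric(n$position$y))
  )
  list(graph = graph, positions = positions)
}

#' Export the graph as GraphML
#'
#' Written through igraph's GraphML writer with `itype`, `n_evidences` and
#' `sources` edge attributes and `is_driver`, `driver_class`, `level`
#' vertex attributes.
#'
#' @param graph An `interaction_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Export the documented edge-list TSV
#'
#' Columns: `src`, `dst`, `itype`, `n_evidences`, `sources`
#' (semicolon-joined source databases).
#'
#' @param graph An `interaction_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(graph, path) {
  readr::write_tsv(tidy.interaction_graph(graph), path, progress = FALSE)
  invisible(path)
}

#' Export Neo4j bulk-import CSVs
#'
#' Writes `nodes.csv` (`symbol:ID`, `:LABEL` — `Gene` or `Gene;Driver` —,
#' `level`, `driver_class`) and `relationships.csv` (`:START_ID`,
#' `:END_ID`, `:TYPE` — the interaction type upper-cased —,
#' `n_evidences:int`) in the property-graph bulk loader layout. No
#' database needs to be present.
#'
#' @param graph An `interaction_graph`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the two file paths, invisibly.
#' @export
export_neo4j_bulk <- function(graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- graph_nodes(graph)
  node_df <- tibble(
    `symbol:ID` = nodes$symbol,
    `:LABEL` = ifelse(nodes$is_driver, "Gene;Driver", "Gene"),
    level = level_label(nodes$level),
    driver_class = nodes$driver_class
  )
  edges <- graph_edges(graph)
  rel_df <- tibble(
    `:START_ID` = edges$src,
    `:END_ID` = edges$dst,
    `:TYPE` = toupper(edges$itype),
    `n_evidences:int` = n_evidences(edges)
  )
  node_path <- file.path(dir, "nodes.csv")
  rel_path <- file.path(dir, "relationships.csv")
  readr::write_csv(node_df, node_path, progress = FALSE)
  readr::write_csv(rel_df, rel_path, progress = FALSE)
  invisible(c(nodes = node_path, relationships = rel_path))
}
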