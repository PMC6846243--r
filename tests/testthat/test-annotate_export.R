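test_that("annotation layers project values without touching topology", {
  g <- mk_graph("A->B")
  h0 <- skelnet:::topology_hash(g)
  g <- attach_layer(g, "expr", c(A = 2.5))
  expect_equal(graph_nodes(g)$expr, c(2.5, 0))
  expect_equal(skelnet:::topology_hash(g), h0)

  g2 <- attach_layer(g, "expr", c(A = 2.5))
  expect_equal(graph_nodes(g2), graph_nodes(g))

  g3 <- attach_layer(g, "fold", c(B = -1.5), default = 1)
  expect_setequal(layer_names(g3), c("expr", "fold"))
  expect_equal(active_layer(g3), "expr")
  g3 <- set_active_layer(g3, "fold")
  expect_equal(active_layer(g3), "fold")
  expect_equal(skelnet:::topology_hash(g3), h0)

  expect_error(attach_layer(g, "bad", c(A = Inf)), "A")
  expect_error(set_active_layer(g, "nope"), "no such")
})

test_that("variant counts attach as non-negative node metadata", {
  g <- mk_graph("A->B")
  g <- set_variant_counts(g, c(A = 7L))
  expect_equal(graph_nodes(g)$variant_count,
               c(7L, NA_integer_))
  expect_error(set_variant_counts(g, c(A = -1L)), ">= 0")
})

grid_positions <- function(g, jitter = 0) {
  syms <- graph_symbols(g)
  tibble::tibble(symbol = syms, x = seq_along(syms) + jitter,
                 y = rev(seq_along(syms)) - jitter)
}

test_that("sessions round-trip nodes, edges, annotations and positions exactly", {
  dir <- withr::local_tempdir()
  wex <- worked_example()
  g <- build_graph(wex$edges, wex$drivers, extra_symbols = wex$extra_symbols)
  lv <- expand_levels(g, build_skeleton(g))
  g <- set_levels(g, lv)
  g <- attach_layer(g, "retina_absolute", wex$expression)
  pos <- grid_positions(g)
  pos$x[1] <- 1e-9
  pos$y[2] <- -2.000000000000004
  p <- file.path(dir, "session.json")
  save_session(g, pos, p)
  s <- load_session(p)
  expect_identical(graph_nodes(s$graph), graph_nodes(g))
  expect_equal(graph_edges(s$graph), graph_edges(g))
  got_pos <- s$positions[match(pos$symbol, s$positions$symbol), ]
  expect_identical(got_pos$x, pos$x)
  expect_identical(got_pos$y, pos$y)
  expect_equal(s$metadata$active_layer, "retina_absolute")
})

test_that("sessions round-trip extreme coordinates bit-exactly", {
  dir <- withr::local_tempdir()
  for (seed in 1:20) {
    set.seed(seed)
    rd <- rand_digraph(seed, n_max = 8)
    g <- rand_graph_obj(rd)
    pos <- tibble::tibble(
      symbol = graph_symbols(g),
      x = runif(length(graph_symbols(g)), -1e9, 1e9) *
        10^sample(-12:12, length(graph_symbols(g)), replace = TRUE),
      y = rnorm(length(graph_symbols(g))))
    p <- file.path(dir, sprintf("s%d.json", seed))
    save_session(g, pos, p)
    s <- load_session(p)
    idx <- match(pos$symbol, s$positions$symbol)
    expect_identical(s$positions$x[idx], pos$x)
    expect_identical(s$positions$y[idx], pos$y)
    expect_setequal(paste(graph_edges(s$graph)$src,
                          graph_edges(s$graph)$dst,
                          graph_edges(s$graph)$itype),
                    paste(graph_edges(g)$src, graph_edges(g)$dst,
                          graph_edges(g)$itype))
  }
})

test_that("saving demands a position for every node, loading rejects junk", {
  dir <- withr::local_tempdir()
  g <- mk_graph("A->B")
  pos <- tibble::tibble(symbol = "A", x = 0, y = 0)
  expect_error(save_session(g, pos, file.path(dir, "s.json")), "B")
  bad <- file.path(dir, "bad.json")
  writeLines("{\"who\": 1}", bad)
  expect_error(load_session(bad), "not a session")

  empty <- build_graph(interaction_tbl())
  p <- file.path(dir, "empty.json")
  save_session(empty, tibble::tibble(symbol = character(), x = numeric(),
                                     y = numeric()), p)
  s <- load_session(p)
  expect_equal(nrow(graph_nodes(s$graph)), 0L)
})

test_that("cytoscape export emits schema-valid elements and re-imports", {
  g <- build_graph(dplyr::bind_rows(
    mk_edges("A->B", itype = "physical"),
    mk_edges("A->B", itype = "genetic")), drivers = "A")
  g <- attach_layer(g, "expr", c(A = 1.25))
  doc <- export_cytoscape_json(g, positions = grid_positions(g))
  expect_equal(length(doc$elements$nodes), 2L)
  expect_equal(length(doc$elements$edges), 2L)
  itypes <- vapply(doc$elements$edges, function(e) e$data$itype, "")
  expect_setequal(itypes, c("physical", "genetic"))

  h0 <- skelnet:::topology_hash(g)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cy.json")
  export_cytoscape_json(g, positions = grid_positions(g), path = p)
  imp <- import_cytoscape_json(p)
  expect_equal(skelnet:::topology_hash(imp$graph), h0)
  expect_equal(nrow(imp$positions), 2L)
  expect_equal(graph_nodes(imp$graph)$expr,
               graph_nodes(g)$expr)

  lone <- build_graph(interaction_tbl(), drivers = "X")
  doc1 <- export_cytoscape_json(lone)
  expect_equal(length(doc1$elements$nodes), 1L)
  expect_equal(length(doc1$elements$edges), 0L)
})

test_that("neo4j bulk export writes conserving node/relationship CSVs", {
  dir <- withr::local_tempdir()
  g <- mk_graph("A->B", drivers = "A", extra_symbols = "Z")
  paths <- export_neo4j_bulk(g, dir)
  nodes <- readr::read_csv(paths["nodes"], show_col_types = FALSE)
  rels <- readr::read_csv(paths["relationships"], show_col_types = FALSE)
  expect_equal(nrow(nodes), 3L)
  expect_equal(nrow(rels), 1L)
  expect_equal(nodes$`:LABEL`[nodes$`symbol:ID` == "A"], "Gene;Driver")
  expect_equal(rels$`:TYPE`, "PHYSICAL")
  expect_true("Z" %in% nodes$`symbol:ID`)
})

test_that("graphml and edge-list exports are pure and faithful", {
  dir <- withr::local_tempdir()
  wex <- worked_example()
  g <- build_graph(wex$edges, wex$drivers, extra_symbols = wex$extra_symbols)
  h0 <- skelnet:::topology_hash(g)
  gml <- file.path(dir, "g.graphml")
  export_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(graph_nodes(g)))
  expect_equal(igraph::ecount(back), nrow(graph_edges(g)))

  tsv <- file.path(dir, "edges.tsv")
  export_edge_list(g, tsv)
  el <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(el), nrow(graph_edges(g)))
  expect_equal(names(el), c("src", "dst", "itype", "n_evidences", "sources"))
  expect_equal(skelnet:::topology_hash(g), h0)
})
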