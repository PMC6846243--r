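Package: skelnet
Title: Driver-Gene Interactome Skeleton Networks, Level Expansion and Path Queries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease-gene interaction networks from heterogeneous
    interaction sources (BioGRID-style experiment tables, STRING-style
    evidence-channel tables and text-mining output), resolves gene symbols
    to official nomenclature, reduces the directed evidence multigraph to a
    skeleton of all shortest paths between disease driver genes, expands the
    skeleton in parent/child levels until saturation, and answers three
    query types over the levelled network (direct interactors, all shortest
    paths between two genes, shortest connections from a gene to a network
    level). Includes numeric annotation layers, session save/restore with
    exact layout positions, exports to Cytoscape.js JSON, GraphML, edge-list
    TSV and Neo4j bulk-import CSV, and a deterministic synthetic-fixture
    generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    readr,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
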