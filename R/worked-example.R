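#' Hand-crafted worked-example network
#'
#' A small fixed dataset built in code, shaped like a levelled disease
#' network in miniature: a skeleton core of three connected driver genes
#' and their shortest-path connectors (including a parallel
#' physical+genetic edge pair), two expansion shells that saturate at
#' level 2, a self-referencing island reachable only in the whole graph,
#' one isolated non-driver gene and one driver gene with no interactions
#' at all (hence unconnected). The expected level table was worked out by
#' hand and ships with the object, so it serves both documentation and
#' smoke tests.
#'
#' @return A list with `edges` (directed-interaction tibble), `drivers`
#'   (symbol/driver_class tibble), `extra_symbols` (the isolated
#'   non-driver gene, to pass to [build_graph()]), `expression` (a named
#'   numeric example annotation layer) and `expected`: `skeleton_nodes`,
#'   `skeleton_edge_count`, `unconnected_drivers`, `saturation_level` (2)
#'   and `levels` (symbol/level tibble, `NA` = whole-graph only).
#' @examples
#' wex <- worked_example()
#' g <- build_graph(wex$edges, wex$drivers, extra_symbols = wex$extra_symbols)
#' sk <- build_skeleton(g)
#' lv <- expand_levels(g, sk)
#' lv$saturation_level
#' @export
worked_example <- function() {
  bg <- function(system) evidence_tbl("biogrid", system)
  st <- evidence_tbl("string", "experimental", score = 500)
  pp <- function(pmid) evidence_tbl("ppaxe", "text-mining",
                                    reference = pmid, score = 0.9)
  phys <- bg("two hybrid")
  e <- list(
    # skeleton core: shortest paths among DRV1, DRV2, DRV3
    list("DRV1", "CONA", "physical", phys),
    list("CONA", "DRV2", "physical", phys),
    list("DRV1", "CONB", "physical", st),
    list("CONB", "DRV2", "physical", st),
    list("DRV2", "DRV3", "genetic", bg("dosage lethality")),
    list("DRV2", "DRV3", "physical", st),   # parallel typed edge
    list("DRV3", "CONC", "physical", phys),
    list("CONC", "DRV1", "physical", phys),
    # first expansion shell
    list("DRV1", "SH1A", "physical", phys),
    list("SH1B", "DRV2", "physical", st),
    list("DRV3", "SH1C", "physical", phys),
    list("SH1D", "CONA", "physical", phys),
    list("CONC", "SH1E", "physical", st),
    list("SH1F", "DRV3", "physical", phys),
    list("SH1A", "SH1B", "unknown", pp("11111111")),  # within-level link
    list("SH1C", "SH1E", "physical", phys),           # within-level link
    # second expansion shell
    list("SH1A", "SH2A", "physical", phys),
    list("SH2B", "SH1D", "physical", st),
    list("SH1E", "SH2C", "physical", phys),
    list("SH2E", "SH1F", "physical", phys),
    list("SH2A", "SH2C", "unknown", pp("22222222")),  # within-level link
    # whole-graph island with a self-reference
    list("ISL1", "ISL2", "physical", phys),
    list("ISL2", "ISL1", "physical", phys),
    list("ISL1", "ISL1", "unknown", pp("33333333")),
    list("ISL2", "ISL3", "physical", phys)
  )
  edges <- interaction_tbl(
    src = map_chr(e, 1), dst = map_chr(e, 2), itype = map_chr(e, 3),
    evidence = map(e, 4))
  drivers <- tibble(
    symbol = c("DRV1", "DRV2", "DRV3", "DRV4"),
    driver_class = c("syndromic", "non_syndromic", "both", "syndromic"))
  symbols <- c(unique(c(edges$src, edges$dst)), "DRV4", "ISO1")
  level_map <- c(
    DRV1 = 0L, DRV2 = 0L, DRV3 = 0L, CONA = 0L, CONB = 0L, CONC = 0L,
    SH1A = 1L, SH1B = 1L, SH1C = 1L, SH1D = 1L, SH1E = 1L, SH1F = 1L,
    SH2A = 2L, SH2B = 2L, SH2C = 2L, SH2E = 2L)
  levels <- tibble(
    symbol = symbols,
    level = unname(level_map[symbols]))
  expression <- setNames(round(seq(2, 8, length.out = length(symbols)), 2),
                         sort(symbols, method = "radix"))
  list(
    edges = edges,
    drivers = drivers,
    extra_symbols = "ISO1",
    expression = expression,
    expected = list(
      skeleton_nodes = c("CONA", "CONB", "CONC", "DRV1", "DRV2", "DRV3"),
      skeleton_edge_count = 8L,
      unconnected_drivers = "DRV4",
      saturation_level = 2L,
      levels = levels
    )
  )
}
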