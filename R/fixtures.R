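#' Specification for a synthetic interactome fixture
#'
#' The generator writes deterministic synthetic inputs in the three source
#' dialects plus driver/alias tables, with ground truth recorded in a
#' manifest, so every pipeline stage is testable without downloads. The
#' random-graph model is a directed Erdős–Rényi backbone over undirected
#' interaction records, plus planted driver-to-driver chains (directed
#' genetic records through fresh intermediate genes) so known shortest
#' paths exist by construction.
#'
#' @param seed Integer RNG seed; mandatory, so identical specs produce
#'   byte-identical output directories.
#' @param n_genes Number of genes (default 30).
#' @param n_drivers Number of driver genes (>= 2, default 4).
#' @param p_edge Probability of an interaction record per unordered gene
#'   pair in the backbone (default 0.06).
#' @param frac_genetic,frac_unknown Fractions of backbone records that are
#'   genetic (directed, curated-source) and unknown (text-mining); the
#'   remainder are physical.
#' @param alias_rate Fraction of genes written under an alias in the
#'   source files (default 0.1).
#' @param n_isolated Number of genes that receive no interaction (default
#'   2).
#' @param planted_chains Integer vector of driver-to-driver chain lengths
#'   (edges; default `c(2, 3)`), laid cyclically over the driver list.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_genes = 30, n_drivers = 4, p_edge = 0.06,
                         frac_genetic = 0.2, frac_unknown = 0.15,
                         alias_rate = 0.1, n_isolated = 2,
                         planted_chains = c(2, 3)) {
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    n_drivers >= 2, n_drivers <= n_genes,
    n_drivers + n_isolated <= n_genes,
    p_edge >= 0, p_edge <= 1,
    frac_genetic >= 0, frac_unknown >= 0, frac_genetic + frac_unknown <= 1,
    alias_rate >= 0, alias_rate <= 1,
    all(planted_chains >= 1)
  )
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_drivers = as.integer(n_drivers), p_edge = p_edge,
         frac_genetic = frac_genetic, frac_unknown = frac_unknown,
         alias_rate = alias_rate, n_isolated = as.integer(n_isolated),
         planted_chains = as.integer(planted_chains)),
    class = "fixture_spec")
}

HUMAN_TAXID <- 9606L
MOUSE_TAXID <- 10090L

#' Generate a synthetic fixture directory
#'
#' Writes `biogrid.tsv`, `string_links.tsv`, `string_actions.tsv`,
#' `ppaxe.tsv`, `drivers.tsv`, `aliases.tsv`, `expression.tsv`,
#' `sources.yaml` (a ready-to-use ingest configuration) and
#' `manifest.json`. Alongside the real records the generator injects rows
#' every parser must drop: non-human interactions, evidence-free
#' protein-links records, below-threshold and non-official text-mining
#' records. The manifest records the expected per-source parser output
#' (with aliases as written), the canonical merged edge list, and
#' independently computed skeleton/level ground truth.
#'
#' Ground truth for the skeleton and levels is computed through igraph
#' distance matrices (shortest-path membership by the distance criterion;
#' levels as undirected distance from the skeleton node set), a code path
#' fully independent of the package's own BFS machinery.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  genes <- sprintf("GEN%04d", seq_len(spec$n_genes))
  drivers <- genes[seq_len(spec$n_drivers)]
  driver_classes <- sample(c("syndromic", "non_syndromic", "both"),
                           spec$n_drivers, replace = TRUE)
  isolated <- if (spec$n_isolated > 0)
    genes[(spec$n_genes - spec$n_isolated + 1L):spec$n_genes] else character()
  pool <- setdiff(genes, isolated)

  # planted driver chains: directed genetic records through fresh
  # intermediates, so driver pairs have connecting paths by construction
  free <- setdiff(pool, drivers)
  records <- list()
  for (i in seq_along(spec$planted_chains)) {
    len <- spec$planted_chains[i]
    a <- drivers[1L + (i - 1L) %% spec$n_drivers]
    b <- drivers[1L + i %% spec$n_drivers]
    need <- len - 1L
    if (need > length(free)) {
      abort("impossible fixture spec: planted chains need more intermediate genes than available")
    }
    mids <- if (need > 0) sample(free, need) else character()
    free <- setdiff(free, mids)
    chain <- c(a, mids, b)
    for (j in seq_len(len)) {
      records[[length(records) + 1L]] <- list(
        a = chain[j], b = chain[j + 1L], itype = "genetic",
        source = "biogrid", direction = "a_to_b",
        system = "dosage lethality")
    }
  }

  # Erdős–Rényi backbone of interaction records over the non-isolated pool
  pairs <- utils::combn(pool, 2)
  hit <- stats::runif(ncol(pairs)) < spec$p_edge
  for (k in which(hit)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    u <- stats::runif(1)
    if (u < spec$frac_genetic) {
      if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
      records[[length(records) + 1L]] <- list(
        a = a, b = b, itype = "genetic", source = "biogrid",
        direction = "a_to_b",
        system = sample(c("dosage lethality", "synthetic lethality",
                          "dosage rescue"), 1))
    } else if (u < spec$frac_genetic + spec$frac_unknown) {
      records[[length(records) + 1L]] <- list(
        a = a, b = b, itype = "unknown", source = "ppaxe",
        direction = "both",
        score = round(stats::runif(1, 0.5, 1), 3),
        pmid = as.character(sample(10000000:30000000, 1)))
    } else if (stats::runif(1) < 0.5) {
      records[[length(records) + 1L]] <- list(
        a = a, b = b, itype = "physical", source = "biogrid",
        direction = "both",
        system = sample(c("two hybrid", "affinity capture-ms", "fret",
                          "co-crystal structure"), 1))
    } else {
      dir_tag <- sample(c("both", "both", "a_to_b", "b_to_a"), 1)
      records[[length(records) + 1L]] <- list(
        a = a, b = b, itype = "physical", source = "string",
        direction = dir_tag,
        experimental = sample(c(0:9 * 100L, 50L), 1),
        database = sample(c(0L, 0L, 400L, 900L), 1))
    }
  }
  # a kept record must have evidence in at least one qualifying channel
  records <- map(records, function(r) {
    if (identical(r$source, "string") &&
        (r$experimental %||% 0) == 0 && (r$database %||% 0) == 0) {
      r$experimental <- 100L
    }
    r
  })

  # aliases: a fraction of genes appear under an alias in the source files
  n_alias <- floor(spec$alias_rate * spec$n_genes)
  aliased <- if (n_alias > 0) sample(genes, n_alias) else character()
  alias_of <- setNames(genes, genes)
  alias_of[aliased] <- paste0(tolower(aliased), "-a")
  alias_df <- tibble(alias = unname(alias_of), official_symbol = genes)

  write_fixture_files(records, out_dir, alias_of, drivers, driver_classes,
                      genes, spec)
  manifest <- fixture_manifest(spec, records, alias_of, drivers,
                               driver_classes, genes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(manifest)
}

# expected directed edges emitted by the parsers for one record; `symbols`
# maps canonical -> as-written (identity for the canonical truth)
record_edges <- function(r, symbols = NULL) {
  a <- if (is.null(symbols)) r$a else unname(symbols[[r$a]])
  b <- if (is.null(symbols)) r$b else unname(symbols[[r$b]])
  if (r$direction == "a_to_b") {
    tibble(src = a, dst = b, itype = r$itype, source_db = r$source)
  } else if (r$direction == "b_to_a") {
    tibble(src = b, dst = a, itype = r$itype, source_db = r$source)
  } else {
    tibble(src = c(a, b), dst = c(b, a), itype = r$itype,
           source_db = r$source)
  }
}

write_fixture_files <- function(records, out_dir, alias_of, drivers,
                                driver_classes, genes, spec) {
  w <- function(sym) unname(alias_of[sym])
  by_source <- split(records, map_chr(records, "source"))

  bg <- by_source$biogrid %||% list()
  bg_rows <- bind_rows(map(bg, function(r) tibble(
    symbol_a = w(r$a), symbol_b = w(r$b),
    taxid_a = HUMAN_TAXID, taxid_b = HUMAN_TAXID,
    experiment_system = r$system, itype_label = NA_character_)))
  # injected rows the parser must drop: non-human interactors
  junk_pool <- genes[seq_len(min(4, length(genes)))]
  bg_junk <- tibble(
    symbol_a = c(w(junk_pool[1]), "Foreign1"),
    symbol_b = c("MouseGene1", w(junk_pool[2])),
    taxid_a = c(HUMAN_TAXID, MOUSE_TAXID),
    taxid_b = c(MOUSE_TAXID, HUMAN_TAXID),
    experiment_system = "two hybrid", itype_label = NA_character_)
  readr::write_tsv(bind_rows(bg_rows, bg_junk),
                   file.path(out_dir, "biogrid.tsv"), progress = FALSE)

  st <- by_source$string %||% list()
  st_rows <- bind_rows(map(st, function(r) tibble(
    symbol_a = w(r$a), symbol_b = w(r$b),
    taxid_a = HUMAN_TAXID, taxid_b = HUMAN_TAXID,
    experimental = r$experimental, database = r$database,
    textmining = 150L)))
  st_junk <- tibble(
    symbol_a = w(junk_pool[3:4]), symbol_b = w(junk_pool[c(1, 2)]),
    taxid_a = HUMAN_TAXID, taxid_b = HUMAN_TAXID,
    experimental = 0L, database = 0L, textmining = 700L)
  readr::write_tsv(bind_rows(st_rows, st_junk),
                   file.path(out_dir, "string_links.tsv"), progress = FALSE)

  directed <- st[map_chr(st, "direction") != "both"]
  act_rows <- bind_rows(map(directed, function(r) tibble(
    symbol_a = w(r$a), symbol_b = w(r$b), direction = r$direction)))
  act_junk <- tibble(symbol_a = "NOPAIR1", symbol_b = "NOPAIR2",
                     direction = "a_to_b")
  readr::write_tsv(bind_rows(act_rows, act_junk),
                   file.path(out_dir, "string_actions.tsv"),
                   progress = FALSE)

  pp <- by_source$ppaxe %||% list()
  pp_rows <- bind_rows(map(pp, function(r) tibble(
    symbol_a = w(r$a), symbol_b = w(r$b), score = r$score, pmid = r$pmid)))
  pp_junk <- tibble(
    symbol_a = c(w(junk_pool[1]), w(junk_pool[2]), "XYZZY123"),
    symbol_b = c(w(junk_pool[2]), w(junk_pool[3]), w(junk_pool[4])),
    score = c(0.10, 0.25, 0.99), pmid = c("1", "2", "3"))
  readr::write_tsv(bind_rows(pp_rows, pp_junk),
                   file.path(out_dir, "ppaxe.tsv"), progress = FALSE)

  readr::write_tsv(tibble(symbol = drivers, driver_class = driver_classes),
                   file.path(out_dir, "drivers.tsv"), progress = FALSE)
  readr::write_tsv(tibble(alias = unname(alias_of),
                          official_symbol = names(alias_of)),
                   file.path(out_dir, "aliases.tsv"), progress = FALSE)
  readr::write_tsv(tibble(symbol = genes,
                          value = round(stats::rlnorm(length(genes), 3, 1),
                                        3)),
                   file.path(out_dir, "expression.tsv"), progress = FALSE)
  yaml::write_yaml(list(
    taxid = HUMAN_TAXID,
    biogrid = list(path = "biogrid.tsv"),
    string = list(links = "string_links.tsv",
                  actions = "string_actions.tsv"),
    ppaxe = list(path = "ppaxe.tsv", score_threshold = 0.5),
    aliases = "aliases.tsv"
  ), file.path(out_dir, "sources.yaml"))
}

fixture_manifest <- function(spec, records, alias_of, drivers,
                             driver_classes, genes) {
  # per-source expected parser output: biogrid/string carry the symbols as
  # written (aliases included); the text-mining parser resolves, so its
  # expectation is canonical
  raw_syms <- alias_of
  per_source <- map(c(biogrid = "biogrid", string = "string",
                      ppaxe = "ppaxe"), function(s) {
    recs <- records[map_chr(records, "source") == s]
    syms <- if (s == "ppaxe") setNames(genes, genes) else raw_syms
    if (length(recs) == 0) {
      tibble(src = character(), dst = character(), itype = character(),
             source_db = character())
    } else {
      bind_rows(map(recs, record_edges, symbols = syms))
    }
  })
  canonical <- bind_rows(map(records, record_edges))
  truth <- fixture_ground_truth(canonical, genes, drivers)
  list(
    spec = unclass(spec),
    genes = genes,
    drivers = tibble(symbol = drivers, driver_class = driver_classes),
    n_records = length(records),
    edges_by_source = per_source,
    edges_canonical = canonical,
    skeleton = truth$skeleton,
    levels = truth$levels,
    saturation_level = truth$saturation_level
  )
}

# independent ground truth through igraph distance matrices
fixture_ground_truth <- function(canonical, genes, drivers) {
  simple <- unique(canonical[, c("src", "dst")])
  g <- igraph::graph_from_data_frame(simple, directed = TRUE,
                                     vertices = genes)
  d <- igraph::distances(g, mode = "out")
  in_skel <- setNames(rep(FALSE, length(genes)), genes)
  skel_edge <- rep(FALSE, nrow(simple))
  for (a in drivers) {
    for (b in setdiff(drivers, a)) {
      dd <- d[a, b]
      if (!is.finite(dd)) next
      in_skel <- in_skel | (is.finite(d[a, genes]) & is.finite(d[genes, b]) &
                              d[a, genes] + d[genes, b] == dd)
      skel_edge <- skel_edge |
        (is.finite(d[a, simple$src]) & is.finite(d[simple$dst, b]) &
           d[a, simple$src] + 1 + d[simple$dst, b] == dd)
    }
  }
  skeleton_nodes <- sort(genes[in_skel], method = "radix")
  reach <- map_chr(drivers, function(dr) {
    others <- setdiff(drivers, dr)
    if (any(is.finite(d[dr, others])) || any(is.finite(d[others, dr])))
      dr else NA_character_
  })
  unconnected <- sort(drivers[is.na(reach)], method = "radix")

  if (length(skeleton_nodes) > 0) {
    du <- igraph::distances(igraph::as_undirected(g), mode = "all")
    lev <- apply(du[skeleton_nodes, genes, drop = FALSE], 2, min)
    levels <- ifelse(is.finite(lev), suppressWarnings(as.integer(lev)),
                     NA_integer_)
    saturation <- if (any(is.finite(lev))) max(levels, na.rm = TRUE) else 0L
  } else {
    levels <- rep(NA_integer_, length(genes))
    saturation <- 0L
  }
  list(
    skeleton = list(
      nodes = skeleton_nodes,
      edges = tibble(src = simple$src[skel_edge],
                     dst = simple$dst[skel_edge]),
      unconnected_drivers = unconnected),
    levels = tibble(symbol = genes, level = unname(levels)),
    saturation_level = as.integer(saturation)
  )
}
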