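#' Experiment-system to interaction-type map
#'
#' Interaction records that lack an explicit physical/genetic label can
#' often be typed from the experiment system that detected them: assays such
#' as two-hybrid or co-crystal structure demonstrate a physical contact,
#' while dosage-lethality-style assays demonstrate a genetic interaction.
#' Systems present in neither set deliberately map to no deduction
#' (`"unknown"`), never to a guess.
#'
#' @param physical_systems,genetic_systems Character vectors of experiment
#'   system names (matched case-insensitively). The two sets must be
#'   disjoint.
#' @return An object of class `experiment_type_map`.
#' @export
experiment_type_map <- function(physical_systems, genetic_systems) {
  physical_systems <- tolower(trimws(physical_systems))
  genetic_systems <- tolower(trimws(genetic_systems))
  both <- intersect(physical_systems, genetic_systems)
  if (length(both) > 0) {
    abort(paste0("experiment systems mapped to both types: ",
                 paste(both, collapse = ", ")))
  }
  structure(list(physical = physical_systems, genetic = genetic_systems),
            class = "experiment_type_map")
}

#' @rdname experiment_type_map
#' @details `default_experiment_type_map()` covers the common experiment
#'   systems of curated interaction databases.
#' @export
default_experiment_type_map <- function() {
  experiment_type_map(
    physical_systems = c(
      "affinity capture-luminescence", "affinity capture-ms",
      "affinity capture-rna", "affinity capture-western",
      "co-crystal structure", "co-fractionation", "co-purification",
      "far western", "fret", "pca", "protein-peptide",
      "proximity label-ms", "reconstituted complex", "two hybrid"
    ),
    genetic_systems = c(
      "dosage growth defect", "dosage lethality", "dosage rescue",
      "negative genetic", "phenotypic enhancement", "phenotypic suppression",
      "positive genetic", "synthetic growth defect", "synthetic lethality",
      "synthetic rescue"
    )
  )
}

deduce_itype <- function(label, system, type_map) {
  label <- tolower(trimws(label %||% ""))
  if (!is.na(label) && label %in% c("physical", "genetic")) return(label)
  system <- tolower(trimws(system %||% ""))
  if (!is.na(system) && system %in% type_map$physical) return("physical")
  if (!is.na(system) && system %in% type_map$genetic) return("genetic")
  "unknown"
}

ingest_result <- function(edges, report) {
  attr(edges, "ingest_report") <- report
  edges
}

#' Kept/dropped counts from a parser
#'
#' @param edges A directed-interaction table returned by one of the source
#'   parsers.
#' @return A one-row tibble of per-source counts.
#' @export
ingest_report <- function(edges) attr(edges, "ingest_report")

#' Parse a BioGRID-style interaction table
#'
#' Reads a tab-separated file with header columns `symbol_a`, `symbol_b`,
#' `taxid_a`, `taxid_b`, `experiment_system`, `itype_label` (gzip files are
#' read transparently). Rows where either organism differs from `taxid` are
#' dropped. The interaction type comes from `itype_label`
#' ("physical"/"genetic") when present, else is deduced from
#' `experiment_system` through `type_map`, else is `"unknown"`.
#'
#' Curated experiment tables rarely state a direction, so physical and
#' unknown records are treated as bidirectional and emitted as two directed
#' edges (A->B and B->A); genetic records are taken as unidirectional in
#' listed order and emit exactly one edge. Each emitted edge carries one
#' evidence record with the experiment system.
#'
#' @param path Path to the TSV file.
#' @param taxid NCBI taxonomy id to keep (default 9606, human).
#' @param type_map An [experiment_type_map()].
#' @return A directed-interaction table (see [interaction_tbl()]) with an
#'   [ingest_report()] attribute.
#' @export
parse_biogrid <- function(path, taxid = 9606,
                          type_map = default_experiment_type_map()) {
  raw <- read_source_tsv(path, c("symbol_a", "symbol_b", "taxid_a",
                                 "taxid_b", "experiment_system",
                                 "itype_label"))
  malformed <- !nzchar(raw$symbol_a %|na|% "") | !nzchar(raw$symbol_b %|na|% "") |
    is.na(suppressWarnings(as.numeric(raw$taxid_a))) |
    is.na(suppressWarnings(as.numeric(raw$taxid_b)))
  if (any(malformed)) {
    inform(sprintf("parse_biogrid: skipped %d malformed row(s)",
                   sum(malformed)))
    raw <- raw[!malformed, , drop = FALSE]
  }
  foreign <- as.numeric(raw$taxid_a) != taxid | as.numeric(raw$taxid_b) != taxid
  kept <- raw[!foreign, , drop = FALSE]

  pieces <- pmap(
    list(kept$symbol_a, kept$symbol_b, kept$itype_label,
         kept$experiment_system),
    function(a, b, label, system) {
      itype <- deduce_itype(label, system, type_map)
      ev <- evidence_tbl("biogrid", system %|na|% "")
      emit_directed(a, b, itype,
                    ev, if (itype == "genetic") "a_to_b" else "both")
    }
  )
  edges <- if (length(pieces) == 0) interaction_tbl() else bind_rows(pieces)
  inform(sprintf(
    "parse_biogrid: %d record(s) kept, %d non-matching-taxon, %d malformed",
    nrow(kept), sum(foreign), sum(malformed)))
  ingest_result(edges, tibble(
    source = "biogrid", records_kept = nrow(kept),
    records_dropped = sum(foreign) + sum(malformed),
    edges_emitted = nrow(edges)))
}

#' Parse a STRING-style protein-links table
#'
#' Reads a links TSV with header columns `symbol_a`, `symbol_b`, `taxid_a`,
#' `taxid_b` and one column per evidence channel (`neighborhood`, `fusion`,
#' `cooccurence`, `coexpression`, `experimental`, `database`, `textmining`;
#' scores on the source's 0-1000 scale). Records whose every score across
#' `evidence_channels` is zero are discarded as prediction-only, as are
#' records from other organisms.
#'
#' An optional actions TSV (`symbol_a`, `symbol_b`, `direction` with
#' direction in `a_to_b`/`b_to_a`) supplies directionality; pairs without a
#' direction tag are treated as bidirectional and emit both directed edges.
#' Protein-links are typed `"physical"`: they describe protein-protein
#' association. Each emitted edge carries one evidence record per
#' qualifying channel, with the channel's score.
#'
#' @param links_path Path to the links TSV.
#' @param actions_path Optional path to the actions TSV.
#' @param taxid NCBI taxonomy id to keep.
#' @param evidence_channels Channels that count as evidence (default
#'   `c("experimental", "database")`; prediction channels are excluded).
#' @return A directed-interaction table with an [ingest_report()] attribute.
#' @export
parse_string <- function(links_path, actions_path = NULL, taxid = 9606,
                         evidence_channels = c("experimental", "database")) {
  raw <- read_source_tsv(links_path, c("symbol_a", "symbol_b", "taxid_a",
                                       "taxid_b"))
  channels <- intersect(evidence_channels, names(raw))
  if (length(channels) == 0) {
    abort(paste0("links file has none of the requested evidence channels: ",
                 paste(evidence_channels, collapse = ", ")))
  }
  for (ch in channels) raw[[ch]] <- suppressWarnings(as.numeric(raw[[ch]]))
  malformed <- !nzchar(raw$symbol_a %|na|% "") | !nzchar(raw$symbol_b %|na|% "")
  raw <- raw[!malformed, , drop = FALSE]
  foreign <- as.numeric(raw$taxid_a) != taxid | as.numeric(raw$taxid_b) != taxid
  score_mat <- as.matrix(raw[, channels, drop = FALSE])
  score_mat[is.na(score_mat)] <- 0
  no_evidence <- rowSums(score_mat > 0) == 0
  keep <- !foreign & !no_evidence
  kept <- raw[keep, , drop = FALSE]
  kept_scores <- score_mat[keep, , drop = FALSE]

  direction_of <- make_direction_lookup(actions_path, kept)

  pieces <- map(seq_len(nrow(kept)), function(i) {
    qual <- kept_scores[i, ] > 0
    ev <- evidence_tbl("string", channels[qual],
                       score = as.numeric(kept_scores[i, qual]))
    emit_directed(kept$symbol_a[i], kept$symbol_b[i], "physical", ev,
                  direction_of(kept$symbol_a[i], kept$symbol_b[i]))
  })
  edges <- if (length(pieces) == 0) interaction_tbl() else bind_rows(pieces)
  inform(sprintf(
    "parse_string: %d record(s) kept, %d without evidence, %d non-matching-taxon",
    nrow(kept), sum(no_evidence & !foreign), sum(foreign)))
  ingest_result(edges, tibble(
    source = "string", records_kept = nrow(kept),
    records_dropped = sum(!keep) + sum(malformed),
    edges_emitted = nrow(edges)))
}

# returns function(a, b) -> "both"/"a_to_b"/"b_to_a"; actions rows that
# match no links pair are counted and reported
make_direction_lookup <- function(actions_path, links) {
  if (is.null(actions_path)) return(function(a, b) "both")
  acts <- read_source_tsv(actions_path, c("symbol_a", "symbol_b",
                                          "direction"))
  link_keys <- unique(c(paste(links$symbol_a, links$symbol_b, sep = "\r"),
                        paste(links$symbol_b, links$symbol_a, sep = "\r")))
  orphan <- !(paste(acts$symbol_a, acts$symbol_b, sep = "\r") %in% link_keys)
  if (any(orphan)) {
    inform(sprintf(
      "parse_string: %d action row(s) reference pairs absent from links; ignored",
      sum(orphan)))
    acts <- acts[!orphan, , drop = FALSE]
  }
  tag <- setNames(tolower(acts$direction),
                  paste(acts$symbol_a, acts$symbol_b, sep = "\r"))
  function(a, b) {
    d <- unname(tag[paste(a, b, sep = "\r")])
    if (is.na(d)) d <- flip_direction(unname(tag[paste(b, a, sep = "\r")]))
    if (is.na(d) || !(d %in% c("a_to_b", "b_to_a"))) "both" else d
  }
}

flip_direction <- function(d) {
  if (is.na(d)) return(NA_character_)
  if (d == "a_to_b") "b_to_a" else if (d == "b_to_a") "a_to_b" else d
}

#' Parse a text-mining (PPaxe-style) interaction table
#'
#' Reads a TSV with header columns `symbol_a`, `symbol_b`, `score` (in
#' [0, 1]) and `pmid`. Records scoring below `score_threshold` are dropped.
#' Symbols are resolved through `alias_table` when given (text-mined
#' symbols are frequently aliases or case variants); records where either
#' resolved symbol is absent from `valid_symbols` — the official
#' nomenclature set — are dropped. Text mining recovers no direction, so
#' every surviving record emits both directed edges with type `"unknown"`,
#' each carrying the supporting article's PMID as evidence.
#'
#' @param path Path to the TSV file.
#' @param score_threshold Minimum score to keep, in [0, 1]; default 0.5.
#' @param valid_symbols Character vector of accepted official symbols.
#' @param alias_table Optional [alias_table()] used to resolve symbols
#'   before the validity check; emitted edges use the resolved symbols.
#' @return A directed-interaction table with an [ingest_report()] attribute.
#' @export
parse_ppaxe <- function(path, score_threshold = 0.5, valid_symbols,
                        alias_table = NULL) {
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  raw <- read_source_tsv(path, c("symbol_a", "symbol_b", "score"))
  if (!"pmid" %in% names(raw)) {
    warn("ppaxe file has no pmid column; evidence references left empty")
    raw$pmid <- NA_character_
  }
  raw$score <- suppressWarnings(as.numeric(raw$score))
  low <- is.na(raw$score) | raw$score < score_threshold
  resolve <- function(s) {
    if (!is.null(alias_table)) return(resolve_symbol(s, alias_table))
    ifelse(toupper(s) %in% toupper(valid_symbols),
           valid_symbols[match(toupper(s), toupper(valid_symbols))],
           NA_character_)
  }
  res_a <- resolve(raw$symbol_a)
  res_b <- resolve(raw$symbol_b)
  invalid <- is.na(res_a) | is.na(res_b) |
    !(res_a %in% valid_symbols) | !(res_b %in% valid_symbols)
  keep <- !low & !invalid
  kept_a <- res_a[keep]
  kept_b <- res_b[keep]
  kept_score <- raw$score[keep]
  kept_pmid <- as.character(raw$pmid)[keep]

  pieces <- pmap(list(kept_a, kept_b, kept_score, kept_pmid),
                 function(a, b, s, p) {
                   ev <- evidence_tbl("ppaxe", "text-mining",
                                      reference = p, score = s)
                   emit_directed(a, b, "unknown", ev, "both")
                 })
  edges <- if (length(pieces) == 0) interaction_tbl() else bind_rows(pieces)
  inform(sprintf(
    "parse_ppaxe: %d record(s) kept, %d below score %.2f, %d with unrecognized symbols",
    sum(keep), sum(low), score_threshold, sum(invalid & !low)))
  ingest_result(edges, tibble(
    source = "ppaxe", records_kept = sum(keep),
    records_dropped = sum(!keep), edges_emitted = nrow(edges)))
}

# shared reader: TSV with header, gzip-transparent, all columns character
read_source_tsv <- function(path, required) {
  if (!file.exists(path)) abort(paste0("cannot read source file: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x
}

# NA-safe coalescing for scalar character fields
`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Ingest all sources described by a YAML configuration
#'
#' The configuration holds one block per source with its file path and
#' per-source options, e.g.:
#'
#' ```yaml
#' taxid: 9606
#' biogrid: {path: biogrid.tsv}
#' string: {links: string_links.tsv, actions: string_actions.tsv,
#'          evidence_channels: [experimental, database]}
#' ppaxe: {path: ppaxe.tsv, score_threshold: 0.5}
#' aliases: aliases.tsv
#' ```
#'
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config_path Path to the YAML file.
#' @return A combined, unaliased directed-interaction table; the alias
#'   table used is attached as attribute `"alias_table"`.
#' @export
ingest_sources <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  taxid <- cfg$taxid %||% 9606
  tab <- if (!is.null(cfg$aliases)) read_alias_table(rel(cfg$aliases)) else NULL
  parts <- list()
  if (!is.null(cfg$biogrid)) {
    parts$biogrid <- parse_biogrid(rel(cfg$biogrid$path), taxid = taxid)
  }
  if (!is.null(cfg$string)) {
    parts$string <- parse_string(
      rel(cfg$string$links), actions_path = rel(cfg$string$actions),
      taxid = taxid,
      evidence_channels = unlist(cfg$string$evidence_channels) %||%
        c("experimental", "database"))
  }
  if (!is.null(cfg$ppaxe)) {
    valid <- if (!is.null(tab)) tab$canonical else
      unlist(cfg$ppaxe$valid_symbols)
    parts$ppaxe <- parse_ppaxe(
      rel(cfg$ppaxe$path),
      score_threshold = cfg$ppaxe$score_threshold %||% 0.5,
      valid_symbols = valid, alias_table = tab)
  }
  edges <- bind_rows(parts)
  if (!is.null(tab)) edges <- unalias_edges(edges, tab)
  attr(edges, "alias_table") <- tab
  edges
}
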