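#' Construct an evidence table
#'
#' Every directed interaction carries one or more evidence records that
#' document where it came from: the source database, the experiment system
#' or evidence channel, an optional literature reference (e.g. a PMID) and
#' an optional score.
#'
#' @param source_db Character vector; one of `"biogrid"`, `"string"`,
#'   `"ppaxe"` or `"session"` per record.
#' @param detail Character vector; the experiment system, evidence-channel
#'   name, or `"text-mining"`.
#' @param reference Optional character vector of external references (PMIDs).
#' @param score Optional numeric vector of per-evidence scores.
#' @return A tibble with columns `source_db`, `detail`, `reference`, `score`.
#' @export
evidence_tbl <- function(source_db, detail, reference = NA_character_,
                         score = NA_real_) {
  source_db <- as.character(source_db)
  bad <- setdiff(unique(source_db), SOURCE_DBS)
  if (length(bad) > 0) {
    abort(paste0("unknown evidence source_db: ", paste(bad, collapse = ", ")))
  }
  tibble(
    source_db = source_db,
    detail = as.character(detail),
    reference = as.character(reference),
    score = as.numeric(score)
  )
}

#' Construct a directed-interaction table
#'
#' The package's central tabular container: one row per directed typed edge
#' `src -> dst`, with the supporting evidence held in the `evidence`
#' list-column (one evidence tibble per edge). Parallel edges between the
#' same ordered pair are permitted only when they differ in interaction
#' type; self-loops (`src == dst`) are permitted.
#'
#' @param src,dst Character vectors of gene symbols.
#' @param itype Character vector of interaction types: `"physical"`,
#'   `"genetic"` or `"unknown"`.
#' @param evidence List of evidence tibbles (see [evidence_tbl()]), one per
#'   edge; a single tibble is recycled.
#' @return A tibble with columns `src`, `dst`, `itype`, `evidence`.
#' @export
interaction_tbl <- function(src = character(), dst = character(),
                            itype = character(), evidence = NULL) {
  src <- as.character(src)
  dst <- as.character(dst)
  itype <- as.character(itype)
  n <- length(src)
  stopifnot(length(dst) == n, length(itype) == n)
  if (n > 0 && (any(!nzchar(src)) || any(!nzchar(dst)))) {
    abort("interaction endpoints must be non-empty symbols")
  }
  bad <- setdiff(unique(itype), ITYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown interaction type: ", paste(bad, collapse = ", ")))
  }
  if (is.null(evidence)) {
    evidence <- rep(list(evidence_tbl(character(), character())), n)
  } else if (is_tibble(evidence)) {
    evidence <- rep(list(evidence), n)
  }
  stopifnot(length(evidence) == n)
  tibble(src = src, dst = dst, itype = itype, evidence = evidence)
}

# number of evidence records per edge
n_evidences <- function(edges) {
  if (nrow(edges) == 0) return(integer())
  map_int(edges$evidence, nrow)
}

# collapse duplicate (src, dst, itype) rows, concatenating their evidence
# lists; row order follows first appearance. Evidence records are never
# deduplicated, so evidence counts are conserved.
merge_interactions <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  key <- paste(edges$src, edges$dst, edges$itype, sep = "\r")
  first <- !duplicated(key)
  if (all(first)) return(edges)
  groups <- split(seq_len(nrow(edges)), factor(key, levels = unique(key)))
  merged <- edges[first, , drop = FALSE]
  merged$evidence <- map(groups, function(i) bind_rows(edges$evidence[i]))
  names(merged$evidence) <- NULL
  merged
}

# expand an undirected record into its two directed rows (or one for a
# directed record); `direction` in {"both", "a_to_b", "b_to_a"}
emit_directed <- function(a, b, itype, evidence, direction = "both") {
  if (direction == "a_to_b") {
    interaction_tbl(a, b, itype, list(evidence))
  } else if (direction == "b_to_a") {
    interaction_tbl(b, a, itype, list(evidence))
  } else {
    interaction_tbl(c(a, b), c(b, a), c(itype, itype),
                    list(evidence, evidence))
  }
}
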