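#' Alias-to-official-symbol table
#'
#' Interaction sources refer to the same gene under different names; before
#' graph construction every symbol is rewritten ("unaliased") to a single
#' official nomenclature symbol. Matching is case-insensitive, since
#' text-mining output in particular carries mixed-case variants. A
#' canonical symbol always resolves to itself; an alias mapping to two
#' different canonical symbols is an error.
#'
#' @param canonical Character vector of official symbols.
#' @param aliases Optional two-column data frame (`alias`,
#'   `official_symbol`) of additional alias rows; every `official_symbol`
#'   must be in `canonical`.
#' @return An object of class `alias_table` with elements `canonical`
#'   (character vector) and `map` (named character vector keyed by
#'   upper-cased alias).
#' @export
alias_table <- function(canonical, aliases = NULL) {
  canonical <- unique(as.character(canonical))
  if (any(!nzchar(canonical))) abort("canonical symbols must be non-empty")
  map <- setNames(canonical, toupper(canonical))
  if (!is.null(aliases)) {
    aliases <- as_tibble(aliases)
    names(aliases)[1:2] <- c("alias", "official_symbol")
    missing <- setdiff(unique(aliases$official_symbol), canonical)
    if (length(missing) > 0) {
      abort(paste0("alias targets not in canonical set: ",
                   paste(missing, collapse = ", ")))
    }
    key <- toupper(aliases$alias)
    dup <- tapply(aliases$official_symbol, key,
                  function(v) length(unique(v)) > 1)
    if (any(dup)) {
      abort(paste0("alias mapped to more than one official symbol: ",
                   paste(names(dup)[dup], collapse = ", ")))
    }
    clash <- key %in% toupper(canonical) &
      toupper(aliases$official_symbol) != key
    if (any(clash)) {
      abort(paste0("alias collides with a canonical symbol: ",
                   paste(aliases$alias[clash], collapse = ", ")))
    }
    map <- c(map, setNames(aliases$official_symbol, key))
    map <- map[!duplicated(names(map))]
  }
  structure(list(canonical = canonical, map = map), class = "alias_table")
}

#' Read an alias table from a two-column TSV
#'
#' The file needs header columns `alias` and `official_symbol`. The
#' canonical set is the union of all official symbols (plus `canonical`,
#' when given).
#'
#' @param path Path to the TSV.
#' @param canonical Optional extra official symbols with no alias rows.
#' @return An [alias_table()].
#' @export
read_alias_table <- function(path, canonical = NULL) {
  x <- read_source_tsv(path, c("alias", "official_symbol"))
  alias_table(unique(c(canonical, x$official_symbol)), x)
}

#' Resolve symbols to their official form
#'
#' @param symbols Character vector of symbols (canonical, alias, or any
#'   case variant thereof).
#' @param table An [alias_table()].
#' @return Character vector of official symbols, `NA` where a symbol is
#'   unknown. Absence is a value: callers decide whether to drop or keep.
#' @export
resolve_symbol <- function(symbols, table) {
  stopifnot(inherits(table, "alias_table"))
  out <- unname(table$map[toupper(as.character(symbols))])
  out[!nzchar(symbols %|na|% "")] <- NA_character_
  out
}

#' Rewrite interaction endpoints to official symbols
#'
#' All endpoints are resolved through `table`; edges that collapse onto the
#' same `(src, dst, itype)` after rewriting are merged with their evidence
#' concatenated, so no evidence record of a surviving edge is lost. Edges
#' with an unresolvable endpoint are dropped when `drop_unknown = TRUE`
#' (the default), else kept verbatim and flagged in a logical `unresolved`
#' column.
#'
#' The operation is idempotent: unaliasing an already-canonical table is
#' the identity.
#'
#' @param edges A directed-interaction table.
#' @param table An [alias_table()].
#' @param drop_unknown Drop edges with an unresolvable endpoint?
#' @return The rewritten table, with a `renamed`/`dropped`/`merged` count
#'   report attached (see [unalias_report()]).
#' @export
unalias_edges <- function(edges, table, drop_unknown = TRUE) {
  if (nrow(edges) == 0) {
    return(structure(edges, unalias_report = tibble(
      renamed = 0L, dropped = 0L, merged = 0L)))
  }
  res_src <- resolve_symbol(edges$src, table)
  res_dst <- resolve_symbol(edges$dst, table)
  unresolved <- is.na(res_src) | is.na(res_dst)
  renamed <- sum((res_src != edges$src | res_dst != edges$dst) & !unresolved)
  out <- edges
  out$src <- ifelse(unresolved, edges$src, res_src)
  out$dst <- ifelse(unresolved, edges$dst, res_dst)
  dropped <- 0L
  if (drop_unknown) {
    dropped <- sum(unresolved)
    out <- out[!unresolved, , drop = FALSE]
  } else {
    out$unresolved <- unresolved
  }
  n_before <- nrow(out)
  out <- merge_interactions(out)
  report <- tibble(renamed = as.integer(renamed),
                   dropped = as.integer(dropped),
                   merged = as.integer(n_before - nrow(out)))
  structure(out, unalias_report = report)
}

#' @rdname unalias_edges
#' @export
unalias_report <- function(edges) attr(edges, "unalias_report")
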