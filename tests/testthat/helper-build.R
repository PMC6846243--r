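# terse edge-table builder: mk_edges("A->B", "B->C") with one evidence
# record per edge
mk_edges <- function(..., itype = "physical", source_db = "biogrid",
                     detail = "two hybrid") {
  specs <- c(...)
  if (length(specs) == 0) return(interaction_tbl())
  parts <- strsplit(specs, "->", fixed = TRUE)
  src <- vapply(parts, `[`, "", 1)
  dst <- vapply(parts, `[`, "", 2)
  itype <- rep_len(itype, length(src))
  interaction_tbl(src, dst, itype,
                  lapply(seq_along(src),
                         function(i) evidence_tbl(source_db, detail)))
}

mk_graph <- function(..., drivers = NULL, itype = "physical",
                     extra_symbols = NULL) {
  build_graph(mk_edges(..., itype = itype), drivers,
              extra_symbols = extra_symbols)
}

path_strings <- function(paths) paths$path

# strip report attributes so edge tables compare on content
bare_edges <- function(x, cols = c("src", "dst", "itype")) {
  tibble::as_tibble(lapply(setNames(cols, cols), function(cl) x[[cl]]))
}

# write a small TSV fixture in a temp dir
write_tsv_tmp <- function(df, name, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, name)
  readr::write_tsv(df, p, progress = FALSE)
  p
}
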