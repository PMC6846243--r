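biogrid_file <- function(rows, dir) {
  write_tsv_tmp(rows, "biogrid.tsv", dir)
}

bg_row <- function(a, b, taxa = 9606, taxb = 9606, system = "fret",
                   label = NA_character_) {
  tibble::tibble(symbol_a = a, symbol_b = b, taxid_a = as.character(taxa),
                 taxid_b = as.character(taxb),
                 experiment_system = system, itype_label = label)
}

test_that("biogrid parsing types, filters and directs records", {
  dir <- withr::local_tempdir()
  rows <- dplyr::bind_rows(
    bg_row("G1", "G2", system = "FRET"),                  # physical, undirected
    bg_row("G1", "G2", system = "dosage lethality"),      # genetic, directed
    bg_row("G1", "G3", taxb = 10090),                     # non-human: dropped
    bg_row("G4", "G5", system = "mystery assay"),         # unknown system
    bg_row("G6", "G7", system = "mystery assay",
           label = "physical")                            # explicit label wins
  )
  edges <- suppressMessages(parse_biogrid(biogrid_file(rows, dir)))

  fret <- edges[edges$itype == "physical" & edges$src %in% c("G1", "G2") &
                  edges$dst %in% c("G1", "G2"), ]
  expect_setequal(paste(fret$src, fret$dst), c("G1 G2", "G2 G1"))

  gen <- edges[edges$itype == "genetic", ]
  expect_equal(nrow(gen), 1L)
  expect_equal(c(gen$src, gen$dst), c("G1", "G2"))

  expect_false("G3" %in% c(edges$src, edges$dst))

  unk <- edges[edges$itype == "unknown", ]
  expect_setequal(paste(unk$src, unk$dst), c("G4 G5", "G5 G4"))

  lab <- edges[edges$src %in% c("G6", "G7"), ]
  expect_true(all(lab$itype == "physical"))
  expect_true(all(vapply(edges$evidence, nrow, 1L) == 1L))
  expect_equal(edges$evidence[[1]]$source_db, "biogrid")
})

test_that("biogrid skips malformed rows and errors on unreadable files", {
  dir <- withr::local_tempdir()
  rows <- dplyr::bind_rows(
    bg_row("G1", "G2"),
    bg_row("G3", NA_character_),
    bg_row("G4", "G5", taxa = "notanumber"))
  expect_message(edges <- parse_biogrid(biogrid_file(rows, dir)),
                 "malformed")
  expect_equal(sort(unique(c(edges$src, edges$dst))), c("G1", "G2"))
  expect_error(suppressMessages(parse_biogrid(file.path(dir, "no.tsv"))),
               "no.tsv")
})

string_files <- function(links, actions = NULL, dir) {
  lp <- write_tsv_tmp(links, "links.tsv", dir)
  ap <- if (!is.null(actions)) write_tsv_tmp(actions, "actions.tsv", dir)
  list(links = lp, actions = ap)
}

st_row <- function(a, b, experimental = 0, database = 0, textmining = 0,
                   taxa = 9606, taxb = 9606) {
  tibble::tibble(symbol_a = a, symbol_b = b, taxid_a = taxa, taxid_b = taxb,
                 experimental = experimental, database = database,
                 textmining = textmining)
}

test_that("string parsing keeps evidence-backed pairs and applies directions", {
  dir <- withr::local_tempdir()
  links <- dplyr::bind_rows(
    st_row("G1", "G2", experimental = 210, textmining = 500),
    st_row("G1", "G3", textmining = 900),             # prediction only: dropped
    st_row("G4", "G5", experimental = 150),           # directed via actions
    st_row("G6", "G7", database = 700, taxb = 10090)  # non-human
  )
  actions <- tibble::tibble(symbol_a = c("G4", "ZZ1"),
                            symbol_b = c("G5", "ZZ2"),
                            direction = c("a_to_b", "a_to_b"))
  f <- string_files(links, actions, dir)
  msgs <- capture_messages(edges <- parse_string(f$links, f$actions))
  expect_match(paste(msgs, collapse = "\n"), "absent from links")

  expect_setequal(paste(edges$src, edges$dst),
                  c("G1 G2", "G2 G1", "G4 G5"))
  expect_true(all(edges$itype == "physical"))
  ev <- edges$evidence[[which(edges$src == "G1")]]
  expect_equal(ev$detail, "experimental")
  expect_equal(ev$score, 210)
})

test_that("string evidence-channel set is configurable", {
  dir <- withr::local_tempdir()
  links <- st_row("G1", "G2", textmining = 900)
  f <- string_files(links, dir = dir)
  strict <- suppressMessages(parse_string(f$links))
  loose <- suppressMessages(
    parse_string(f$links, evidence_channels = c("experimental", "database",
                                                "textmining")))
  expect_equal(nrow(strict), 0L)
  expect_equal(nrow(loose), 2L)
})

test_that("ppaxe parsing filters by score and official symbols, assumes bidirectionality", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(
    symbol_a = c("G1", "G1", "p53", "G1"),
    symbol_b = c("G2", "G2", "G2", "XYZZY"),
    score = c(0.95, 0.30, 0.80, 0.95),
    pmid = c("123", "124", "125", "126"))
  p <- write_tsv_tmp(rows, "ppaxe.tsv", dir)
  tab <- alias_table(c("G1", "G2", "TP53"),
                     data.frame(alias = "p53", official_symbol = "TP53"))
  edges <- suppressMessages(
    parse_ppaxe(p, score_threshold = 0.5,
                valid_symbols = tab$canonical, alias_table = tab))

  expect_setequal(paste(edges$src, edges$dst),
                  c("G1 G2", "G2 G1", "TP53 G2", "G2 TP53"))
  expect_true(all(edges$itype == "unknown"))
  refs <- sort(unique(unlist(lapply(edges$evidence, `[[`, "reference"))))
  expect_equal(refs, c("123", "125"))
})

test_that("ppaxe warns once when the pmid column is missing", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(symbol_a = "G1", symbol_b = "G2", score = 0.9)
  p <- write_tsv_tmp(rows, "ppaxe.tsv", dir)
  expect_warning(
    edges <- suppressMessages(parse_ppaxe(p, valid_symbols = c("G1", "G2"))),
    "pmid")
  expect_true(all(is.na(unlist(lapply(edges$evidence, `[[`, "reference")))))
})

test_that("parsing is deterministic and respects the 2-undirected/1-directed rule", {
  dir <- withr::local_tempdir()
  rows <- dplyr::bind_rows(
    bg_row("A", "B", system = "two hybrid"),
    bg_row("B", "C", system = "dosage rescue"),
    bg_row("C", "D", system = "mystery"))
  p <- biogrid_file(rows, dir)
  e1 <- suppressMessages(parse_biogrid(p))
  e2 <- suppressMessages(parse_biogrid(p))
  expect_identical(e1[, c("src", "dst", "itype")],
                   e2[, c("src", "dst", "itype")])
  # 2 undirected records (physical + unknown) and 1 genetic
  expect_equal(nrow(e1), 2L * 2L + 1L)
})

test_that("ingest_sources drives all three parsers from a YAML config", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 42, n_genes = 20, n_drivers = 3)
  manifest <- suppressMessages(generate_fixture(spec, dir))
  edges <- suppressMessages(ingest_sources(file.path(dir, "sources.yaml")))
  got <- dplyr::arrange(
    tibble::tibble(src = edges$src, dst = edges$dst, itype = edges$itype),
    src, dst, itype)
  want <- manifest$edges_canonical
  want <- dplyr::arrange(
    dplyr::distinct(want[, c("src", "dst", "itype")]), src, dst, itype)
  expect_equal(got, want)
})
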