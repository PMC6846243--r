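test_that("skeleton keeps exactly the nodes on driver-pair shortest paths", {
  g <- mk_graph("D1->X", "X->D2", "D1->Y", drivers = c("D1", "D2"))
  sk <- build_skeleton(g)
  expect_setequal(sk$nodes, c("D1", "X", "D2"))
  expect_false("Y" %in% sk$nodes)
  expect_equal(nrow(sk$edges), 2L)

  # every parallel shortest path belongs to the skeleton, not just one
  g2 <- mk_graph("D1->A", "A->D2", "D1->B", "B->D2",
                 drivers = c("D1", "D2"))
  sk2 <- build_skeleton(g2)
  expect_setequal(sk2$nodes, c("A", "B", "D1", "D2"))
})

test_that("drivers with no path either way are reported unconnected", {
  g <- mk_graph("D1->X", "D2->Y", drivers = c("D1", "D2"))
  sk <- build_skeleton(g)
  expect_equal(nrow(sk$edges), 0L)
  expect_equal(length(sk$nodes), 0L)
  expect_setequal(sk$unconnected_drivers, c("D1", "D2"))
  expect_error(build_skeleton(g, drivers = "D1"), "at least 2")
})

test_that("skeleton equals the brute-force union-of-paths oracle", {
  for (seed in 1:60) {
    rd <- rand_digraph(seed)
    g <- rand_graph_obj(rd)
    sk <- build_skeleton(g, rd$drivers)
    want <- oracle_skeleton(rd$edges, rd$drivers)
    expect_identical(sk$nodes, want$nodes, info = paste("seed", seed))
    got_edges <- sort(paste(sk$edges$src, sk$edges$dst, sk$edges$itype))
    want_edges <- sort(paste(want$edges$src, want$edges$dst,
                             want$edges$itype))
    expect_identical(got_edges, want_edges, info = paste("seed", seed))
    expect_identical(sk$unconnected_drivers, want$unconnected,
                     info = paste("seed", seed))
  }
})

test_that("level expansion walks parent/child shells to saturation", {
  # chain D1->D2<-A<-B<-C: A, B, C are picked up at levels 1, 2, 3
  g <- mk_graph("D1->D2", "A->D2", "B->A", "C->B",
                drivers = c("D1", "D2"))
  sk <- build_skeleton(g)
  lv <- expand_levels(g, sk)
  expect_equal(lv$saturation_level, 3L)
  lo <- setNames(lv$level_of$level, lv$level_of$symbol)
  expect_equal(unname(lo[c("D1", "D2", "A", "B", "C")]),
               c(0L, 0L, 1L, 2L, 3L))
})

test_that("a skeleton covering all connected nodes saturates at once", {
  g <- mk_graph("D1->D2", drivers = c("D1", "D2"))
  lv <- expand_levels(g, build_skeleton(g))
  expect_equal(lv$saturation_level, 0L)
  expect_equal(nrow(lv$per_level), 1L)
})

test_that("isolated nodes stay in the whole graph at every level", {
  g <- mk_graph("D1->D2", drivers = c("D1", "D2"), extra_symbols = "Z")
  lv <- expand_levels(g, build_skeleton(g))
  expect_true(is.na(lv$level_of$level[lv$level_of$symbol == "Z"]))
  w <- whole_graph(g, lv)
  expect_setequal(w$nodes, c("D1", "D2", "Z"))
})

test_that("levels are monotone, reconcile with the whole graph, and are a fixed point", {
  for (seed in 1:20) {
    rd <- rand_digraph(seed)
    g <- rand_graph_obj(rd)
    sk <- build_skeleton(g, rd$drivers)
    lv <- expand_levels(g, sk)
    pl <- lv$per_level
    expect_true(all(diff(pl$total_nodes) >= 0))
    expect_true(all(diff(pl$total_edges) >= 0))
    expect_equal(pl$total_nodes, cumsum(pl$new_nodes))
    expect_equal(pl$total_edges, cumsum(pl$new_edges))
    # every node at level k >= 1 has a neighbor at level k - 1
    lo <- setNames(lv$level_of$level, lv$level_of$symbol)
    for (s in names(lo)[!is.na(lo) & lo >= 1]) {
      nb <- node_neighbors(g, s, "both")
      expect_true(any(lo[nb] == lo[[s]] - 1L, na.rm = TRUE),
                  info = paste("seed", seed, s))
    }
    # fixed point: expanding the saturation set adds nothing
    sat_nodes <- lv$level_of$symbol[!is.na(lv$level_of$level)]
    if (length(sat_nodes) > 0) {
      again <- expand_levels(g, sat_nodes)
      expect_equal(again$saturation_level, 0L)
    }
    # whole-graph conservation: levelled totals + whole remainder
    w <- whole_graph(g, lv)
    sat <- pl[nrow(pl), ]
    expect_equal(length(w$nodes) - sat$total_nodes,
                 sum(is.na(lv$level_of$level)))
    rest <- setdiff(w$nodes, sat_nodes)
    ed <- graph_edges(g)
    extra <- sum(ed$src %in% rest | ed$dst %in% rest)
    expect_equal(nrow(ed), sat$total_edges + extra)
    # drivers are level 0 or unconnected
    drv <- lv$level_of[lv$level_of$is_driver, ]
    expect_true(all(drv$level == 0L | drv$symbol %in% sk$unconnected_drivers |
                      is.na(drv$level)))
  }
})

test_that("every edge beyond the saturation set touches a whole-level node", {
  wex <- worked_example()
  g <- build_graph(wex$edges, wex$drivers, extra_symbols = wex$extra_symbols)
  lv <- expand_levels(g, build_skeleton(g))
  lo <- setNames(lv$level_of$level, lv$level_of$symbol)
  ed <- graph_edges(g)
  beyond <- ed[is.na(lo[ed$src]) | is.na(lo[ed$dst]), ]
  expect_true(all(is.na(lo[beyond$src]) & is.na(lo[beyond$dst])))
  expect_gt(nrow(beyond), 0)
})

test_that("max_level stops expansion early without claiming saturation", {
  g <- mk_graph("D1->D2", "A->D2", "B->A", "C->B",
                drivers = c("D1", "D2"))
  lv <- expand_levels(g, build_skeleton(g), max_level = 1)
  expect_true(is.na(lv$saturation_level))
  expect_equal(max(lv$level_of$level, na.rm = TRUE), 1L)
})

test_that("the worked example matches its hand-computed ground truth", {
  wex <- worked_example()
  g <- build_graph(wex$edges, wex$drivers, extra_symbols = wex$extra_symbols)
  sk <- build_skeleton(g)
  expect_identical(sk$nodes, wex$expected$skeleton_nodes)
  expect_equal(nrow(sk$edges), wex$expected$skeleton_edge_count)
  expect_identical(sk$unconnected_drivers, wex$expected$unconnected_drivers)
  lv <- expand_levels(g, sk)
  expect_equal(lv$saturation_level, wex$expected$saturation_level)
  want <- wex$expected$levels
  got <- lv$level_of[match(want$symbol, lv$level_of$symbol), ]
  expect_equal(got$level, want$level)
  # designed-in: a self-loop only reachable in the whole graph
  ed <- graph_edges(g)
  loops <- ed[ed$src == ed$dst, ]
  expect_gt(nrow(loops), 0)
  lo <- setNames(lv$level_of$level, lv$level_of$symbol)
  expect_true(all(is.na(lo[loops$src])))
})

test_that("level tables export as documented TSVs", {
  dir <- withr::local_tempdir()
  wex <- worked_example()
  g <- build_graph(wex$edges, wex$drivers, extra_symbols = wex$extra_symbols)
  lv <- expand_levels(g, build_skeleton(g))
  p1 <- write_level_table(lv, file.path(dir, "levels.tsv"))
  p2 <- write_level_summary(lv, file.path(dir, "summary.tsv"))
  t1 <- readr::read_tsv(p1, show_col_types = FALSE)
  expect_setequal(names(t1), c("symbol", "level", "is_driver",
                               "driver_class"))
  expect_true("whole" %in% t1$level)
  t2 <- readr::read_tsv(p2, show_col_types = FALSE)
  expect_equal(names(t2), c("level", "new_nodes", "new_edges",
                            "total_nodes", "total_edges"))
})
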