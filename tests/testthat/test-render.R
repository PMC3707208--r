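render_fixture <- function() {
  h <- worked_hierarchy()
  tr <- tree_transformation(h, seed = 2)
  lay <- force_layout(tr, layout_params(seed = 1, max_iterations = 60))
  list(h = h, tr = tr, lay = lay)
}

test_that("SVG contains one element per visible node and tree edge", {
  fx <- render_fixture()
  f <- withr::local_tempfile(fileext = ".svg")
  render_svg(fx$tr, fx$lay, style_map(), f)
  svg <- readLines(f)
  n_nodes <- length(grep('class="node', svg))
  n_edges <- length(grep('class="edge"', svg))
  # 8 base dots + 3 cluster glyphs; root hidden
  expect_equal(n_nodes, 11)
  # tree has 11 edges, of which 1 root->top is hidden with the root
  expect_equal(n_edges, 10)
  expect_length(grep("__root__", svg), 0)
})

test_that("rendering is byte-deterministic and highlights are overlaid", {
  fx <- render_fixture()
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_svg(fx$tr, fx$lay, style_map(), f1)
  render_svg(fx$tr, fx$lay, style_map(), f2)
  expect_identical(readLines(f1), readLines(f2))

  hl <- rbind(c("a1", "a2"), c("a1", "a3"), c("a1", "a4"))
  render_svg(fx$tr, fx$lay, style_map(), f2, highlights = hl)
  expect_length(grep('class="highlight"', readLines(f2)), 3)
})

test_that("rendering fails clearly when a node has no position", {
  fx <- render_fixture()
  bad <- fx$lay
  bad$positions <- bad$positions[rownames(bad$positions) != "a1", ]
  f <- withr::local_tempfile(fileext = ".svg")
  expect_error(render_svg(fx$tr, bad, style_map(), f), "a1")
})

test_that("neighbour highlighting distinguishes base and cluster nodes", {
  fx <- render_fixture()
  # base node: its original edges only (a1: 3 clique edges + bridge)
  e_a1 <- highlight_neighbors(fx$tr, "a1")
  expect_equal(nrow(e_a1), 4)
  expect_true(all(e_a1 == "a1" | apply(e_a1, c(1, 2), startsWith, "a") |
                    e_a1 == "b1"))

  # cluster node over one K4: 4 membership edges down, 1 membership edge
  # up into the level-2 cluster, 1 inter-cluster edge, plus 1 original
  # member-to-outside edge (the bridge)
  cn <- unique(fx$h$membership[sprintf("a%d", 1:4)])
  e_cn <- highlight_neighbors(fx$tr, cn)
  expect_equal(nrow(e_cn), 7)
  expect_error(highlight_neighbors(fx$tr, "nope"), "unknown node")

  # isolated base node has no highlightable edges
  g <- network_graph(c(sprintf("a%d", 1:4), "solo"),
                     clique_edges(sprintf("a%d", 1:4)))
  h <- create_multilevel_clusters(g, gamma_schedule(1.0),
                                  cluster_search_params(1.0, 3, 10, seed = 1))
  tr <- tree_transformation(h, seed = 1)
  expect_equal(nrow(highlight_neighbors(tr, "solo")), 0)
})

test_that("cluster drill-down reveals exactly the hidden internal edges", {
  fx <- render_fixture()
  cn <- unique(fx$h$membership[sprintf("a%d", 1:4)])
  internal <- cluster_internal_edges(fx$tr, cn)
  expect_equal(nrow(internal), 6)  # the K4
  expect_true(all(c(internal) %in% sprintf("a%d", 1:4)))

  top <- unique(fx$h$membership[c("C1_1", "C1_2")])
  e2 <- cluster_internal_edges(fx$tr, top)
  expect_equal(nrow(e2), 1)  # single inter-cluster edge
  expect_error(cluster_internal_edges(fx$tr, "a1"), "not a cluster")
})

test_that("drill-down edges reconstruct the original edge set exactly", {
  fixtures <- list(worked_hierarchy(),
                   create_multilevel_clusters(
                     planted_partition(3, 8, 0.9, 0.05, seed = 3)$graph,
                     gamma_schedule(c(0.5, 0.7)),
                     cluster_search_params(0.5, 3, 15, seed = 2)))
  for (h in fixtures) {
    tr <- tree_transformation(h, seed = 6)
    base_keys <- gammaclust:::edge_keys(level_subgraph(h, 0))
    nms <- igraph::V(h$graph)$name
    lvl <- setNames(igraph::V(h$graph)$level, nms)
    kind <- setNames(igraph::V(h$graph)$kind, nms)
    recon <- character(0)
    for (cn in nms[lvl == 1 & kind == "cluster"]) {
      ie <- cluster_internal_edges(tr, cn)
      if (nrow(ie)) recon <- c(recon, paste(pmin(ie[, 1], ie[, 2]),
                                            pmax(ie[, 1], ie[, 2]),
                                            sep = "|"))
    }
    # plus base edges not inside any level-1 cluster (cross-cluster and
    # orphan edges)
    el <- igraph::as_edgelist(level_subgraph(h, 0), names = TRUE)
    covered <- vapply(seq_len(nrow(el)), function(i) {
      ca <- h$membership[el[i, 1]]; cb <- h$membership[el[i, 2]]
      !is.na(ca) && !is.na(cb) && ca == cb
    }, TRUE)
    recon <- c(recon, gammaclust:::edge_keys(level_subgraph(h, 0),
                                             el[!covered, , drop = FALSE]))
    expect_setequal(recon, base_keys)
  }
})

test_that("degree colours bin consistently", {
  st <- star_graph(6)
  col <- degree_color(st)
  expect_equal(length(unique(col[sprintf("l%d", 1:6)])), 1)
  expect_false(col[["c"]] == col[["l1"]])

  k5 <- make_clique(5)
  expect_equal(length(unique(degree_color(k5))), 1)  # regular graph

  expect_length(degree_color(network_graph(character(0))), 0)

  g <- random_gnp(30, 0.2, seed = 3)
  col2 <- degree_color(g)
  deg <- igraph::degree(g)
  for (d in unique(deg)) {
    expect_equal(length(unique(col2[names(which(deg == d))])), 1)
  }
})
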