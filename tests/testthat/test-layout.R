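test_that("edge target lengths follow the level schedule", {
  p <- layout_params(base_edge_length = 10, level_factor = 1.5)
  expect_equal(edge_target_length(0, p), 10)
  expect_equal(edge_target_length(2, p), 22.5)
  expect_error(edge_target_length(-1, p), "non-negative")
  expect_error(layout_params(level_factor = 1.0), "level_factor")
  expect_error(layout_params(repulsion_cutoff_fraction = 0))
})

test_that("initial positions are concentric with inherited segments", {
  # K4 under one cluster: root -> C1_1 -> four symmetric base children
  h <- create_multilevel_clusters(make_clique(4), gamma_schedule(1.0),
                                  cluster_search_params(1.0, 3, 10, seed = 1))
  tr <- tree_transformation(h, seed = 1)
  p <- layout_params(area = c(1000, 1000), seed = 1)
  pos <- initial_positions(tr, p)
  centre <- c(500, 500)
  expect_equal(unname(pos[tr$root, ]), centre, tolerance = 1e-3)

  # children of one node lie on the circle of their depth
  r <- sqrt(rowSums((pos[, 1:2] - matrix(centre, nrow(pos), 2,
                                         byrow = TRUE))^2))
  d <- tr$depth[rownames(pos)]
  ring <- unname(r[names(which(d == 1))[1]])
  expect_true(all(abs(r[d == 2] - 2 * ring) < 1))

  # base children split the full segment inherited through the chain:
  # four children -> angular gaps of ~90 degrees
  base <- names(which(d == 2))
  ang <- sort(atan2(pos[base, 2] - centre[2], pos[base, 1] - centre[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(unname(gaps), rep(pi / 2, 4), tolerance = 0.01)
})

test_that("a root-only tree sits at the centre", {
  e <- network_graph(character(0))
  h <- create_multilevel_clusters(e, gamma_schedule(0.5),
                                  cluster_search_params(0.5, 3, 5, seed = 1))
  tr <- tree_transformation(h, seed = 1)
  pos <- initial_positions(tr, layout_params())
  expect_equal(nrow(pos), 1)
})

test_that("force layout is deterministic, finite and area-bounded", {
  h <- worked_hierarchy()
  tr <- tree_transformation(h, seed = 2)
  p <- layout_params(seed = 9, max_iterations = 120)
  l1 <- force_layout(tr, p)
  l2 <- force_layout(tr, p)
  expect_identical(l1$positions, l2$positions)
  expect_true(all(is.finite(l1$positions)))
  expect_true(all(l1$positions >= 0))
  expect_true(all(l1$positions[, 1] <= p$area[1]))
  expect_true(all(l1$positions[, 2] <= p$area[2]))
})

test_that("symmetric star leaves equilibrate at near-equal radii", {
  # star whose centre+leaves form one degree-feasible 0.15-cluster, so the
  # tree is root -> cluster -> 7 symmetric children
  st <- star_graph(6)
  h <- create_multilevel_clusters(st, gamma_schedule(0.15),
                                  cluster_search_params(0.15, 3, 20,
                                                        seed = 2))
  expect_equal(h$n_levels, 1)
  tr <- tree_transformation(h, seed = 1)
  cn <- h$clusters[[1]]
  cnode <- unique(h$membership[cn$members])
  lay <- force_layout(tr, layout_params(seed = 3, max_iterations = 200))
  pos <- lay$positions
  leaves <- setdiff(cn$members, character(0))
  dists <- sqrt(rowSums((pos[leaves, , drop = FALSE] -
                           matrix(pos[cnode, ], length(leaves), 2,
                                  byrow = TRUE))^2))
  expect_lt((max(dists) - min(dists)) / mean(dists), 0.05)
})

test_that("higher-level tree edges come out longer than lower-level ones", {
  h <- create_multilevel_clusters(
    cliques_joined_by_matching(8, 2), gamma_schedule(c(0.5, 0.7)),
    cluster_search_params(0.5, min_size = 2, restarts = 20, seed = 4))
  expect_equal(h$n_levels, 2)
  tr <- tree_transformation(h, seed = 1)
  lay <- force_layout(tr, layout_params(seed = 2, max_iterations = 250))
  pos <- lay$positions
  lv <- gammaclust:::tree_edge_levels(tr)
  len <- vapply(names(tr$parent), function(v)
    sqrt(sum((pos[v, ] - pos[tr$parent[[v]], ])^2)), 0)
  mean_by_level <- tapply(len, lv, mean)
  expect_lt(mean_by_level[["0"]], mean_by_level[["1"]])
})

test_that("convergence flag reflects the displacement criterion", {
  h <- create_multilevel_clusters(make_clique(4), gamma_schedule(1.0),
                                  cluster_search_params(1.0, 3, 10, seed = 1))
  tr <- tree_transformation(h, seed = 1)
  loose <- force_layout(tr, layout_params(convergence_tol = 5,
                                          max_iterations = 500, seed = 1))
  expect_true(loose$converged)
  expect_lt(loose$iterations_run, 500)
  tight <- force_layout(tr, layout_params(convergence_tol = 1e-9,
                                          max_iterations = 5, seed = 1))
  expect_false(tight$converged)
  expect_equal(tight$iterations_run, 5)
})

test_that("the repulsion cutoff is inert for a tree well inside it", {
  h <- create_multilevel_clusters(make_clique(4), gamma_schedule(1.0),
                                  cluster_search_params(1.0, 3, 10, seed = 1))
  tr <- tree_transformation(h, seed = 1)
  base <- layout_params(area = c(300, 300), base_edge_length = 10,
                        max_iterations = 80, seed = 5)
  small <- base; small$repulsion_cutoff_fraction <- 0.95
  big <- base; big$repulsion_cutoff_fraction <- 1.0
  expect_identical(force_layout(tr, small)$positions,
                   force_layout(tr, big)$positions)
})

test_that("positions JSON round-trips through jsonlite", {
  h <- worked_hierarchy()
  tr <- tree_transformation(h, seed = 2)
  lay <- force_layout(tr, layout_params(seed = 1, max_iterations = 50))
  f <- withr::local_tempfile(fileext = ".json")
  write_positions_json(lay, f)
  got <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(names(got), rownames(lay$positions))
  expect_equal(unname(got[["a1"]]), unname(round(lay$positions["a1", ], 6)))
})
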