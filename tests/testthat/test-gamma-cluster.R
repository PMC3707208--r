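test_that("gamma density matches its definition and conventions", {
  k4 <- make_clique(4)
  expect_equal(gamma_density(k4, igraph::V(k4)$name), 1.0)

  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(gamma_density(p3, c("a", "b", "c")), 2 / 3)
  expect_equal(gamma_density(p3, "a"), 1.0)
  expect_error(gamma_density(p3, c("a", "zzz")), "not in graph")

  expect_true(is_gamma_cluster(k4, igraph::V(k4)$name, 1.0))
  expect_false(is_gamma_cluster(p3, c("a", "b", "c"), 0.7))
  expect_true(is_gamma_cluster(p3, c("a", "b", "c"), 0.5))

  # cross-check against the independent edge-list oracle on random sets
  g <- random_gnp(12, 0.4, seed = 9)
  nms <- igraph::V(g)$name
  for (s in 1:10) {
    mem <- withr::with_seed(s, sample(nms, sample(2:8, 1)))
    expect_equal(gamma_density(g, mem), oracle_density(g, mem))
  }
})

test_that("density feasibility is monotone in gamma", {
  g <- random_gnp(15, 0.3, seed = 4)
  nms <- igraph::V(g)$name
  for (s in 1:20) {
    mem <- withr::with_seed(100 + s, sample(nms, sample(2:10, 1)))
    g1 <- withr::with_seed(200 + s, runif(1))
    g2 <- withr::with_seed(300 + s, runif(1, 0, g1))
    if (is_gamma_cluster(g, mem, g1)) {
      expect_true(is_gamma_cluster(g, mem, g2))
    }
  }
})

test_that("exact oracle finds maximum gamma-clusters on small graphs", {
  k5 <- make_clique(5)
  expect_setequal(max_gamma_clique_exact(k5, 1.0), igraph::V(k5)$name)

  cyc <- cycle_graph(letters[1:5])
  expect_length(max_gamma_clique_exact(cyc, 1.0), 2)  # no triangle
  # the full 5-cycle has density 5/10 = 0.5, so all 5 nodes qualify
  expect_setequal(max_gamma_clique_exact(cyc, 0.5), letters[1:5])

  # agreement with an independent brute-force enumeration
  for (s in 1:5) {
    g <- random_gnp(8, 0.45, seed = 40 + s)
    gam <- c(0.6, 0.8, 1.0)[1 + s %% 3]
    expect_length(max_gamma_clique_exact(g, gam),
                  length(oracle_max_set(g, gam)))
  }

  big <- random_gnp(25, 0.1, seed = 1)
  expect_error(max_gamma_clique_exact(big, 1.0), "20 nodes")
})

test_that("construct_dsubg finds planted dense subgraphs", {
  p <- cluster_search_params(1.0, min_size = 3, restarts = 20, seed = 2)
  r <- construct_dsubg(k6_pendant(), p)
  expect_setequal(r$members, sprintf("k%d", 1:6))
  expect_equal(r$density, 1.0)

  two_k5 <- cliques_joined_by_matching(5, 2)
  r2 <- construct_dsubg(two_k5, p)
  expect_length(r2$members, 5)  # brute force: max clique is one K5
  expect_true(all(startsWith(r2$members, "q1_")) ||
                all(startsWith(r2$members, "q2_")))

  edgeless <- network_graph(sprintf("n%d", 1:10))
  expect_null(construct_dsubg(edgeless,
                              cluster_search_params(0.5, 3, 10, seed = 1)))

  # determinism: identical seed, identical result
  g <- random_gnp(30, 0.3, seed = 6)
  pa <- cluster_search_params(0.7, 3, 15, seed = 99)
  expect_identical(construct_dsubg(g, pa), construct_dsubg(g, pa))
})

test_that("GRASP never beats, and usually matches, the exact oracle", {
  match <- 0
  for (s in 1:40) {
    g <- random_gnp(6 + (s %% 7), 0.5, seed = 500 + s)
    exact <- max_gamma_clique_exact(g, 1.0)
    r <- construct_dsubg(g, cluster_search_params(1.0, 2, 50, seed = s))
    sz <- if (is.null(r)) 1 else length(r$members)
    expect_lte(sz, length(exact))
    if (sz == length(exact)) match <- match + 1
  }
  expect_gte(match, 36)  # >= 90% of trials
})

test_that("create_clusters extracts disjoint clusters and stops correctly", {
  a <- sprintf("x%d", 1:4); b <- sprintf("y%d", 1:4)
  g <- network_graph(c(a, b, "iso"),
                     rbind(clique_edges(a), clique_edges(b)))
  cl <- create_clusters(g, cluster_search_params(0.5, 3, 20, seed = 3))
  expect_length(cl, 2)
  mem <- lapply(cl, `[[`, "members")
  expect_setequal(unlist(mem), c(a, b))
  expect_length(intersect(mem[[1]], mem[[2]]), 0)

  tree_g <- path_graph(sprintf("t%d", 1:8))  # triangle-free
  expect_length(create_clusters(tree_g,
                                cluster_search_params(0.9, 3, 20, seed = 1)),
                0)

  # every emitted cluster satisfies the density bound in the level graph
  for (s in 1:10) {
    g2 <- random_gnp(40, 0.25, seed = 700 + s)
    gam <- c(0.5, 0.7)[1 + s %% 2]
    cl2 <- create_clusters(g2, cluster_search_params(gam, 3, 10, seed = s))
    all_members <- unlist(lapply(cl2, `[[`, "members"))
    expect_equal(anyDuplicated(all_members), 0)
    for (cc in cl2) {
      expect_true(is_gamma_cluster(g2, cc$members, gam))
      expect_gte(cc$density, cc$gamma)
      expect_gte(length(cc$members), 3)
    }
  }
})

test_that("planted partition blocks are recovered with high Jaccard", {
  hits <- 0
  for (s in 1:5) {
    pp <- planted_partition(3, 10, 0.9, 0.02, seed = 60 + s)
    cl <- create_clusters(pp$graph,
                          cluster_search_params(0.7, 4, 30, seed = s))
    blocks <- split(names(pp$blocks), pp$blocks)
    ok <- vapply(blocks, function(bl) {
      any(vapply(cl, function(cc) {
        length(intersect(cc$members, bl)) /
          length(union(cc$members, bl)) >= 0.9
      }, TRUE))
    }, TRUE)
    if (all(ok)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("cluster TSV export has one row per member", {
  cl <- create_clusters(two_k4_one_edge(),
                        cluster_search_params(0.5, 2, 20, seed = 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- write_clusters_tsv(cl, f)
  got <- read.delim(f)
  expect_equal(nrow(got), sum(lengths(lapply(cl, `[[`, "members"))))
  expect_named(got, c("cluster_id", "level", "gamma", "density", "member"))
})

test_that("search parameter validation rejects bad values", {
  expect_error(cluster_search_params(1.2), "gamma")
  expect_error(cluster_search_params(0.5, min_size = 1), "min_size")
  expect_error(cluster_search_params(0.5, restarts = 0), "restarts")
  expect_error(cluster_search_params(0.5, rcl_alpha = 2), "rcl_alpha")
})
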