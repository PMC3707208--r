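# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

clique_edges <- function(ids) t(combn(ids, 2))

make_clique <- function(n, prefix = "v") {
  ids <- sprintf("%s%d", prefix, seq_len(n))
  network_graph(ids, clique_edges(ids))
}

# two K4s joined by a single edge a1-b1: the worked multilevel example
two_k4_one_edge <- function() {
  a <- sprintf("a%d", 1:4); b <- sprintf("b%d", 1:4)
  network_graph(c(a, b), rbind(clique_edges(a), clique_edges(b),
                               c("a1", "b1")))
}

# K6 plus a pendant vertex hanging off k1
k6_pendant <- function() {
  k <- sprintf("k%d", 1:6)
  network_graph(c(k, "p"), rbind(clique_edges(k), c("k1", "p")))
}

path_graph <- function(ids) {
  network_graph(ids, cbind(ids[-length(ids)], ids[-1]))
}

cycle_graph <- function(ids) {
  network_graph(ids, cbind(ids, ids[c(2:length(ids), 1)]))
}

star_graph <- function(n_leaves, centre = "c") {
  leaves <- sprintf("l%d", seq_len(n_leaves))
  network_graph(c(centre, leaves), cbind(centre, leaves))
}

# default worked hierarchy + tree used by several modules
worked_hierarchy <- function(seed = 7) {
  create_multilevel_clusters(two_k4_one_edge(), gamma_schedule(c(0.5, 0.7)),
                             cluster_search_params(0.5, min_size = 2,
                                                   restarts = 20,
                                                   seed = seed))
}

# brute-force density oracle, independent of gamma_density: counts edges
# of the induced subgraph straight from the edge list
oracle_density <- function(graph, members) {
  if (length(members) <= 1) return(1)
  el <- igraph::as_edgelist(graph, names = TRUE)
  inside <- el[, 1] %in% members & el[, 2] %in% members
  sum(inside) / choose(length(members), 2)
}

# brute-force maximum gamma-cluster by subset enumeration (independent of
# max_gamma_clique_exact)
oracle_max_set <- function(graph, gamma) {
  nms <- sort(igraph::V(graph)$name)
  n <- length(nms)
  best <- nms[1]
  for (k in 2:n) {
    sets <- combn(nms, k, simplify = FALSE)
    for (s in sets) {
      if (oracle_density(graph, s) >= gamma && k > length(best)) best <- s
    }
  }
  best
}
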