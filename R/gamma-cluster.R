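# Quasi-clique (gamma-cluster) detection.
#
# A vertex set S is a gamma-cluster when |E(S)| >= gamma * C(|S|, 2), i.e.
# its induced edge density reaches gamma; gamma = 1 recovers cliques.
# Detection uses a GRASP heuristic: a randomized greedy construction seeded
# from high-degree vertices, guided by the potential
#   phi(S) = |E(S)| - gamma * C(|S|, 2)
# (non-negative exactly when S is feasible), followed by a swap-based local
# search, repeated over independent restarts.

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("gamma must be a single number in [0, 1]")
  }
  as.double(gamma)
}

#' Search parameters for gamma-cluster detection
#'
#' @param gamma Required density in `[0, 1]`.
#' @param min_size Minimum cluster size (at least 2; default 3).
#' @param restarts Number of independent GRASP restarts.
#' @param rcl_alpha Fraction of the degree-ranked vertex list eligible as a
#'   randomized starting vertex (restricted candidate list).
#' @param seed Integer seed making the whole search deterministic.
#' @return A `cluster_search_params` list.
#' @export
cluster_search_params <- function(gamma, min_size = 3L, restarts = 20L,
                                  rcl_alpha = 0.2, seed = 1L) {
  gamma <- check_gamma(gamma)
  min_size <- as.integer(min_size)
  restarts <- as.integer(restarts)
  if (min_size < 2L) stop("min_size must be >= 2")
  if (restarts < 1L) stop("restarts must be >= 1")
  if (rcl_alpha < 0 || rcl_alpha > 1) stop("rcl_alpha must be in [0, 1]")
  structure(list(gamma = gamma, min_size = min_size, restarts = restarts,
                 rcl_alpha = rcl_alpha, seed = as.integer(seed)),
            class = "cluster_search_params")
}

new_cluster <- function(members, level, gamma, density) {
  structure(list(members = sort(as.character(members)),
                 level = as.integer(level),
                 gamma = as.double(gamma),
                 density = as.double(density)),
            class = "gamma_cluster")
}

#' @export
print.gamma_cluster <- function(x, ...) {
  cat(sprintf("gamma-cluster: %d members, level %d, density %.3f (gamma %.2f)\n",
              length(x$members), x$level, x$density, x$gamma))
  invisible(x)
}

#' Induced edge density of a vertex set
#'
#' Returns `|E(S)| / C(|S|, 2)`; by convention sets of size 0 or 1 have
#' density 1 so that the minimum-size rule, not the density test, is what
#' excludes singletons.
#'
#' @param graph A network graph.
#' @param members Character vector of node identifiers.
#' @return Density in `[0, 1]`.
#' @export
gamma_density <- function(graph, members) {
  graph <- as_network_graph(graph)
  members <- unique(as.character(members))
  unknown <- setdiff(members, igraph::V(graph)$name)
  if (length(unknown)) stop("members not in graph: ",
                            paste(unknown, collapse = ", "))
  s <- length(members)
  if (s <= 1) return(1.0)
  m <- igraph::ecount(igraph::induced_subgraph(graph, members))
  m / choose(s, 2)
}

#' Test whether a vertex set is a gamma-cluster
#'
#' @inheritParams gamma_density
#' @param gamma Required density.
#' @return `TRUE` iff `gamma_density(graph, members) >= gamma`.
#' @export
is_gamma_cluster <- function(graph, members, gamma) {
  gamma <- check_gamma(gamma)
  gamma_density(graph, members) >= gamma
}

# Internal state used by the GRASP routines: adjacency as integer index
# lists, so the greedy steps are O(deg) updates on a connection counter.
build_adj <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

phi_value <- function(n_edges, size, gamma) {
  n_edges - gamma * choose(size, 2)
}

# One randomized greedy construction + local search. Works on integer
# vertex indices; returns indices of the best feasible set found, or NULL.
#
# Admission is twofold: the potential phi(S + v) must stay non-negative
# AND the entering vertex must itself be reasonably connected to the
# current set (conn[v] >= KAPPA * gamma * |S|). The local condition keeps
# the construction from absorbing a sparsely attached neighbourhood whose
# bulk density still clears gamma — e.g. a second clique reachable over a
# matching — while the slack KAPPA < 1 tolerates members whose degree sits
# slightly under the gamma line inside a genuinely dense cluster. A
# peeling pass applies the same threshold to members; the exact density
# bound is always re-checked before a set is returned.
KAPPA <- 0.75

grasp_once <- function(adj, degs, gamma, min_size, rcl_alpha) {
  n <- length(adj)
  rcl_n <- max(1L, ceiling(rcl_alpha * n))
  rcl <- order(degs, decreasing = TRUE)[seq_len(rcl_n)]
  v0 <- rcl[sample.int(length(rcl), 1L)]

  in_s <- logical(n)
  conn <- integer(n)          # edges from each vertex into S
  s_size <- 0L
  s_edges <- 0L
  add_vertex <- function(v) {
    in_s[v] <<- TRUE
    s_size <<- s_size + 1L
    s_edges <<- s_edges + conn[v]
    conn[adj[[v]]] <<- conn[adj[[v]]] + 1L
  }
  drop_vertex <- function(v) {
    in_s[v] <<- FALSE
    s_size <<- s_size - 1L
    conn[adj[[v]]] <<- conn[adj[[v]]] - 1L
    s_edges <<- s_edges - conn[v]
  }
  admissible <- function(v) {
    conn[v] >= KAPPA * gamma * s_size &&
      phi_value(s_edges + conn[v], s_size + 1L, gamma) >= 0
  }
  grow <- function(allow_repair) {
    repeat {
      cand <- which(!in_s & conn > 0L)
      if (length(cand) == 0L) break
      top <- cand[conn[cand] == max(conn[cand])]
      v <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
      if (admissible(v) || (allow_repair && s_size < min_size)) {
        add_vertex(v)
      } else break
    }
  }
  # remove members until each clears the slacked degree line and the set
  # is density-feasible; dropping a below-line member never lowers phi
  peel <- function() {
    repeat {
      if (s_size <= 1L) break
      members <- which(in_s)
      worst <- members[which.min(conn[members])]
      if (conn[worst] >= KAPPA * gamma * (s_size - 1L) &&
          phi_value(s_edges, s_size, gamma) >= 0) break
      drop_vertex(worst)
    }
  }

  add_vertex(v0)
  grow(allow_repair = TRUE)
  peel()
  grow(allow_repair = FALSE)
  peel()

  # swap phase: trade the weakest member for the best outsider when that
  # strictly raises the potential, then try to grow again
  max_swaps <- 2L * s_size + 10L
  for (i in seq_len(max_swaps)) {
    if (s_size <= min_size) break
    members <- which(in_s)
    worst <- members[which.min(conn[members])]
    phi_before <- phi_value(s_edges, s_size, gamma)
    drop_vertex(worst)
    cand <- setdiff(which(!in_s & conn > 0L), worst)
    if (length(cand) == 0L) { add_vertex(worst); break }
    v <- cand[which.max(conn[cand])]
    add_vertex(v)
    if (phi_value(s_edges, s_size, gamma) > phi_before) {
      grow(allow_repair = FALSE)
      peel()
    } else {
      drop_vertex(v)
      add_vertex(worst)
      break
    }
  }

  if (s_size >= min_size && phi_value(s_edges, s_size, gamma) >= 0) {
    which(in_s)
  } else NULL
}

#' GRASP search for one large gamma-cluster
#'
#' Runs `params$restarts` independent randomized greedy constructions with
#' local search and returns the best feasible cluster found: largest member
#' set, ties broken by higher density, then by lexicographically smallest
#' member set. Deterministic for a fixed `params$seed`.
#'
#' @param graph A network graph (one hierarchy level).
#' @param params A [cluster_search_params()] object.
#' @param level Hierarchy level recorded on the returned cluster.
#' @return A `gamma_cluster`, or `NULL` if no feasible cluster of at least
#'   `min_size` members was found.
#' @export
construct_dsubg <- function(graph, params, level = 1L) {
  stopifnot(inherits(params, "cluster_search_params"))
  graph <- as_network_graph(graph)
  n <- igraph::vcount(graph)
  if (n == 0) stop("graph is empty")
  if (igraph::ecount(graph) == 0) return(NULL)
  adj <- build_adj(graph)
  degs <- lengths(adj)
  names_v <- igraph::V(graph)$name

  best <- NULL
  with_seed(params$seed, {
    for (r in seq_len(params$restarts)) {
      idx <- grasp_once(adj, degs, params$gamma, params$min_size,
                        params$rcl_alpha)
      if (is.null(idx)) next
      members <- sort(names_v[idx])
      dens <- gamma_density(graph, members)
      cand <- new_cluster(members, level, params$gamma, dens)
      if (is.null(best) ||
          length(cand$members) > length(best$members) ||
          (length(cand$members) == length(best$members) &&
           (cand$density > best$density ||
            (cand$density == best$density &&
             paste(cand$members, collapse = "\r") <
             paste(best$members, collapse = "\r"))))) {
        best <- cand
      }
    }
  })
  best
}

#' Extract all disjoint gamma-clusters of one level
#'
#' Repeatedly applies [construct_dsubg()], removing each found cluster's
#' members from the candidate pool, until no further cluster of at least
#' `min_size` members exists. Because extraction works on induced
#' subgraphs, every returned cluster also satisfies the density bound in
#' the original level graph.
#'
#' @inheritParams construct_dsubg
#' @return List of `gamma_cluster` objects with pairwise-disjoint members.
#' @export
create_clusters <- function(graph, params, level = 1L) {
  stopifnot(inherits(params, "cluster_search_params"))
  graph <- as_network_graph(graph)
  clusters <- list()
  pool <- graph
  round <- 0L
  while (igraph::vcount(pool) >= params$min_size &&
         igraph::ecount(pool) > 0) {
    round <- round + 1L
    sub_params <- params
    sub_params$seed <- params$seed + round  # vary restarts between rounds
    cl <- construct_dsubg(pool, sub_params, level = level)
    if (is.null(cl) || length(cl$members) < params$min_size) break
    clusters[[length(clusters) + 1L]] <- cl
    pool <- igraph::delete_vertices(pool, cl$members)
  }
  clusters
}

#' Exact maximum gamma-cluster by exhaustive enumeration
#'
#' Test oracle for the (NP-hard) maximum quasi-clique problem: enumerates
#' vertex subsets from largest cardinality down and returns the first
#' feasible set, breaking ties by lexicographically smallest member set.
#' Guarded to graphs of at most 20 vertices.
#'
#' @param graph A network graph with at most 20 nodes.
#' @param gamma Required density.
#' @return Character vector of member identifiers (possibly a single node).
#' @export
max_gamma_clique_exact <- function(graph, gamma) {
  gamma <- check_gamma(gamma)
  graph <- as_network_graph(graph)
  n <- igraph::vcount(graph)
  if (n > 20) stop("exact search is limited to 20 nodes (got ", n, ")")
  if (n == 0) return(character(0))
  nms <- sort(igraph::V(graph)$name)
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)[nms, nms,
                                                            drop = FALSE]
  for (k in n:1) {
    if (k == 1) return(nms[1])
    need <- gamma * choose(k, 2)
    hits <- combn(n, k, function(idx) {
      sum(adj[idx, idx]) / 2 >= need
    })
    combos <- combn(n, k)
    ok <- which(hits)
    if (length(ok)) {
      # combn enumerates index sets in lexicographic order already
      return(nms[combos[, ok[1]]])
    }
  }
}

#' Write clusters to a TSV file
#'
#' One row per member with columns `cluster_id`, `level`, `gamma`,
#' `density`, `member`.
#'
#' @param clusters List of `gamma_cluster` objects.
#' @param path Output path.
#' @param ids Optional cluster identifiers (default `C<level>_<index>`).
#' @export
write_clusters_tsv <- function(clusters, path, ids = NULL) {
  if (is.null(ids)) {
    ids <- vapply(seq_along(clusters), function(i)
      sprintf("C%d_%d", clusters[[i]]$level, i), "")
  }
  rows <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = ids[i], level = cl$level, gamma = cl$gamma,
               density = cl$density, member = cl$members,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster_id = character(0), level = integer(0),
                       gamma = double(0), density = double(0),
                       member = character(0))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
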