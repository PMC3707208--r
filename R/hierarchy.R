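# Multilevel cluster hierarchy.
#
# Level 0 holds the input graph. Each pass of gamma-cluster detection on
# the current top level adds one layer of cluster nodes: a membership edge
# joins every cluster node to each of its members, and an inter-cluster
# edge joins two cluster nodes whenever any edge exists between their
# member sets one level below. Density requirements grow with the level,
# so the hierarchy tracks increasingly tight structure until a single
# cluster (or none) remains.

#' Per-level gamma schedule
#'
#' @param values Gamma values for levels 1, 2, ...; if more levels are
#'   needed than values supplied, the last value repeats. The default
#'   `c(0.5, 0.7)` uses a slightly looser density on the first level than
#'   on subsequent ones, which works well because induced density grows as
#'   clustering proceeds upwards.
#' @return A `gamma_schedule` object.
#' @export
gamma_schedule <- function(values = c(0.5, 0.7)) {
  values <- vapply(values, check_gamma, 0)
  if (length(values) == 0) stop("schedule must contain at least one gamma")
  if (is.unsorted(values)) {
    warning("gamma schedule is not non-decreasing; ",
            "higher levels are denser, so a growing schedule is advised")
  }
  structure(list(values = values), class = "gamma_schedule")
}

schedule_gamma_at <- function(schedule, level) {
  v <- schedule$values
  v[min(level, length(v))]
}

#' Build the multilevel cluster hierarchy
#'
#' Starting from a base graph (all nodes level 0, kind `"base"`), runs
#' [create_clusters()] level by level with the scheduled gamma, adding
#' cluster nodes (`C<level>_<index>`), membership edges and inter-cluster
#' edges. Nodes left unclustered at a level do not take part in higher
#' levels. Stops when a level yields no cluster or a single cluster node.
#'
#' @param graph Base network graph.
#' @param schedule A [gamma_schedule()].
#' @param params A [cluster_search_params()]; its `gamma` field is ignored
#'   in favour of the schedule.
#' @return A `gamma_hierarchy` list with fields `graph` (the layered
#'   igraph), `clusters`, `membership` (named character: node -> its
#'   cluster node), `n_levels` and `base_nodes`.
#' @export
create_multilevel_clusters <- function(graph, schedule, params) {
  stopifnot(inherits(schedule, "gamma_schedule"),
            inherits(params, "cluster_search_params"))
  graph <- as_network_graph(graph)
  if (any(igraph::V(graph)$level != 0L) ||
      any(igraph::V(graph)$kind != "base")) {
    stop("input must contain only level-0 base nodes")
  }
  h <- graph
  if (igraph::ecount(h) > 0) igraph::E(h)$edge_type <- "base"
  clusters <- list()
  cluster_ids <- character(0)
  membership <- character(0)
  base_names <- igraph::V(graph)$name

  level <- 0L
  current <- graph  # graph of the current top level (its internal edges)
  repeat {
    next_level <- level + 1L
    g_i <- schedule_gamma_at(schedule, next_level)
    p <- params
    p$gamma <- g_i
    p$seed <- params$seed + 1000L * next_level
    found <- create_clusters(current, p, level = next_level)
    if (length(found) == 0) break

    ids <- make_cluster_ids(next_level, length(found), base_names)
    h <- igraph::add_vertices(h, length(found), name = ids,
                              level = next_level, kind = "cluster")
    # membership edges
    mem_edges <- do.call(rbind, lapply(seq_along(found), function(i) {
      cbind(ids[i], found[[i]]$members)
    }))
    h <- igraph::add_edges(h, t(mem_edges),
                           attr = list(edge_type = "membership"))
    membership[mem_edges[, 2]] <- mem_edges[, 1]

    # inter-cluster edges, witnessed by any lower-level edge
    owner <- setNames(rep(seq_along(found), lengths(lapply(found, `[[`,
                                                           "members"))),
                      unlist(lapply(found, `[[`, "members")))
    if (igraph::ecount(current) > 0) {
      el <- igraph::as_edgelist(current, names = TRUE)
      oa <- owner[el[, 1]]; ob <- owner[el[, 2]]
      cross <- !is.na(oa) & !is.na(ob) & oa != ob
      if (any(cross)) {
        pairs <- unique(cbind(pmin(oa[cross], ob[cross]),
                              pmax(oa[cross], ob[cross])))
        h <- igraph::add_edges(h, t(cbind(ids[pairs[, 1]], ids[pairs[, 2]])),
                               attr = list(edge_type = "intercluster"))
      }
    }
    clusters <- c(clusters, found)
    cluster_ids <- c(cluster_ids, ids)
    level <- next_level
    current <- induced_level_graph(h, next_level)
    if (length(found) == 1) break
  }

  structure(list(graph = as_network_graph(h), clusters = clusters,
                 membership = membership, n_levels = level,
                 base_nodes = base_names),
            class = "gamma_hierarchy")
}

make_cluster_ids <- function(level, k, existing) {
  ids <- sprintf("C%d_%d", level, seq_len(k))
  while (any(ids %in% existing)) ids <- paste0("_", ids)
  ids
}

induced_level_graph <- function(h, level) {
  keep <- igraph::V(h)$name[igraph::V(h)$level == level]
  g <- igraph::induced_subgraph(h, keep)
  if (igraph::ecount(g) > 0) {
    g <- igraph::delete_edges(g,
      igraph::E(g)[igraph::E(g)$edge_type == "membership"])
  }
  g
}

#' @export
print.gamma_hierarchy <- function(x, ...) {
  cat(sprintf("gamma hierarchy: %d base nodes, %d clusters over %d level(s)\n",
              length(x$base_nodes), length(x$clusters), x$n_levels))
  invisible(x)
}

#' Subgraph of one hierarchy level
#'
#' Nodes at exactly that level with the intra-level edges (base edges for
#' level 0, inter-cluster edges above); membership edges are excluded.
#'
#' @param hierarchy A `gamma_hierarchy`.
#' @param level Level in `0:n_levels`.
#' @return A network graph.
#' @export
level_subgraph <- function(hierarchy, level) {
  stopifnot(inherits(hierarchy, "gamma_hierarchy"))
  if (level < 0 || level > hierarchy$n_levels) {
    stop("level out of range [0, ", hierarchy$n_levels, "]: ", level)
  }
  induced_level_graph(hierarchy$graph, level)
}

#' Export a hierarchy to GraphML
#'
#' @param hierarchy A `gamma_hierarchy`.
#' @param path Output path.
#' @export
write_hierarchy_graphml <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "gamma_hierarchy"))
  write_graphml(hierarchy$graph, path)
}

# Per-level node/edge/density summary used by the pipeline manifest.
hierarchy_summary <- function(hierarchy) {
  lapply(0:hierarchy$n_levels, function(lv) {
    g <- level_subgraph(hierarchy, lv)
    n <- igraph::vcount(g); m <- igraph::ecount(g)
    list(level = lv, nodes = n, edges = m,
         density = if (n >= 2) m / choose(n, 2) else 1.0)
  })
}
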