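# Tree transformation.
#
# A hidden root node is attached to every top-level cluster node, and a
# breadth-first search from the root over the full layered graph (base,
# inter-cluster and membership edges alike) assigns each node its
# shortest-path distance. Each node keeps a single parent: the cluster
# node containing it when it is a cluster member, otherwise a uniformly
# random neighbour one step closer to the root. Components that contain no
# cluster are unreachable from the root; their nodes are attached to the
# root directly and flagged as orphans.

ROOT_NAME <- "__root__"

#' Transform a hierarchy into a rooted shortest-path tree
#'
#' @param hierarchy A `gamma_hierarchy`.
#' @param seed Integer seed for random tie-breaking among equally close
#'   parents; one seeded generator is shared across the whole pass.
#' @return A `layout_tree` with fields `root`, `parent` (named character),
#'   `depth` (named integer, root at 0), `orphans` (character vector) and
#'   `hierarchy` (the input, retained for drill-down queries).
#' @export
tree_transformation <- function(hierarchy, seed = 1L) {
  stopifnot(inherits(hierarchy, "gamma_hierarchy"))
  h <- hierarchy$graph
  nodes <- igraph::V(h)$name
  root <- ROOT_NAME
  while (root %in% nodes) root <- paste0("_", root)

  top_level <- hierarchy$n_levels
  tops <- nodes[igraph::V(h)$level == top_level &
                  igraph::V(h)$kind == "cluster"]

  g <- igraph::add_vertices(h, 1L, name = root,
                            level = top_level + 1L, kind = "root")
  if (length(tops)) {
    g <- igraph::add_edges(g, rbind(rep(root, length(tops)), tops),
                           attr = list(edge_type = "membership"))
  }

  if (length(nodes) == 0) {
    return(structure(list(root = root, parent = character(0),
                          depth = setNames(0L, root)[0],
                          orphans = character(0), root_depth = 0L,
                          hierarchy = hierarchy, graph = g),
                     class = "layout_tree"))
  }

  dist <- igraph::distances(g, v = root, mode = "all")[1, ]
  parent <- character(0)
  depth <- setNames(rep(NA_integer_, length(nodes)), nodes)
  membership <- hierarchy$membership
  orphans <- character(0)

  with_seed(seed, {
    ord <- nodes[order(dist[nodes], nodes)]
    for (v in ord) {
      d <- dist[v]
      if (!is.finite(d)) {       # no cluster anywhere in v's component
        parent[v] <- root
        depth[v] <- 1L
        orphans <- c(orphans, v)
        next
      }
      depth[v] <- as.integer(d)
      if (d == 1) { parent[v] <- root; next }
      if (v %in% names(membership)) {
        p <- membership[[v]]
        if (dist[p] != d - 1) {
          # cannot happen when inter-cluster edges witness every
          # lower-level adjacency; fall back to a BFS-optimal parent
          warning("membership parent of ", v, " is not distance-minimal")
          nb <- igraph::neighbors(g, v)$name
          cand <- sort(nb[dist[nb] == d - 1])
          p <- if (length(cand) == 1) cand else
            cand[sample.int(length(cand), 1L)]
        }
        parent[v] <- p
      } else {
        nb <- igraph::neighbors(g, v)$name
        cand <- sort(nb[dist[nb] == d - 1])
        parent[v] <- if (length(cand) == 1) cand else
          cand[sample.int(length(cand), 1L)]
      }
    }
  })

  structure(list(root = root, parent = parent,
                 depth = c(setNames(0L, root), depth),
                 orphans = orphans, hierarchy = hierarchy, graph = g),
            class = "layout_tree")
}

#' @export
print.layout_tree <- function(x, ...) {
  cat(sprintf("layout tree: %d nodes (+ hidden root), height %d, %d orphan(s)\n",
              length(x$parent), if (length(x$depth)) max(x$depth) else 0L,
              length(x$orphans)))
  invisible(x)
}

# Tree edges as canonical "u|v" keys (includes root edges and synthetic
# orphan attachments).
tree_edge_keys <- function(tree) {
  if (length(tree$parent) == 0) return(character(0))
  u <- names(tree$parent); v <- unname(tree$parent)
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

#' Hierarchy edges hidden by the tree view
#'
#' The complement of the tree's edge set within the full layered graph
#' (root edges included); these are the edges drill-down queries reveal.
#'
#' @param tree A `layout_tree`.
#' @return Two-column character matrix of hidden edge endpoints.
#' @export
hidden_edges <- function(tree) {
  stopifnot(inherits(tree, "layout_tree"))
  all_keys <- edge_keys(tree$graph)
  hid <- setdiff(all_keys, tree_edge_keys(tree))
  if (length(hid) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  do.call(rbind, strsplit(hid, "|", fixed = TRUE)) |>
    `colnames<-`(c("from", "to"))
}

#' Export a tree over its hierarchy to GraphML
#'
#' Writes the full layered graph with a boolean-like edge attribute
#' `in_tree` (`"true"`/`"false"`).
#'
#' @param tree A `layout_tree`.
#' @param path Output path.
#' @param positions Optional coordinate matrix (see [write_graphml()]).
#' @export
write_tree_graphml <- function(tree, path, positions = NULL) {
  stopifnot(inherits(tree, "layout_tree"))
  g <- tree$graph
  if (igraph::ecount(g) > 0) {
    # synthetic orphan attachments are tree-only edges not present in g
    keys <- edge_keys(g)
    igraph::E(g)$in_tree <- ifelse(keys %in% tree_edge_keys(tree),
                                   "true", "false")
  }
  write_graphml(g, path, positions = positions)
}

#' Export the parent map as TSV (node, parent, depth)
#'
#' @param tree A `layout_tree`.
#' @param path Output path.
#' @export
write_parent_map_tsv <- function(tree, path) {
  stopifnot(inherits(tree, "layout_tree"))
  nodes <- sort(names(tree$parent))
  df <- data.frame(node = nodes, parent = unname(tree$parent[nodes]),
                   depth = unname(tree$depth[nodes]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
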