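# Semantic rendering and drill-down queries.
#
# The default drawing shows only the tree: base nodes coloured by their
# degree in the original graph, cluster nodes as enlarged diamond glyphs
# growing with level, the root hidden. All the edges removed by the tree
# transformation stay available through two queries: the incident edges of
# a selected node (neighbour highlight) and the hidden internal edges of a
# selected cluster.

#' Style map for rendering
#'
#' @param palette Ordered colour ramp for degree bins (low to high).
#' @param n_bins Number of degree quantile bins.
#' @param base_radius Radius of base-node dots.
#' @param cluster_radius_step Additional radius per hierarchy level for
#'   cluster glyphs (sizes strictly increase with level).
#' @param edge_color,membership_color,highlight_color Stroke colours.
#' @return A `style_map` object.
#' @export
style_map <- function(palette = c("#2166ac", "#67a9cf", "#f7f7f7",
                                  "#ef8a62", "#b2182b"),
                      n_bins = 5L, base_radius = 3,
                      cluster_radius_step = 3,
                      edge_color = "#999999",
                      membership_color = "#bbbbbb",
                      highlight_color = "#e41a1c") {
  stopifnot(n_bins >= 1, length(palette) >= n_bins,
            base_radius > 0, cluster_radius_step > 0)
  structure(list(palette = palette, n_bins = as.integer(n_bins),
                 base_radius = base_radius,
                 cluster_radius_step = cluster_radius_step,
                 edge_color = edge_color,
                 membership_color = membership_color,
                 highlight_color = highlight_color),
            class = "style_map")
}

#' Bin node colours by degree in the original graph
#'
#' The distinct degree values are split into up to `n_bins` quantile bins
#' mapped onto an ordered palette. Binning distinct values (rather than
#' raw degrees) keeps the top of a skewed, scale-free-like distribution
#' visible: a single hub still lands in the top bin even though almost
#' all mass sits at small degrees. Equal degrees always share a colour.
#'
#' @param graph The original (level-0) network graph.
#' @param style A [style_map()] object.
#' @return Named character vector of colours.
#' @export
degree_color <- function(graph, style = style_map()) {
  graph <- as_network_graph(graph)
  if (igraph::vcount(graph) == 0) return(setNames(character(0), character(0)))
  deg <- igraph::degree(graph)
  udeg <- sort(unique(deg))
  ubin <- ceiling(seq_along(udeg) / length(udeg) * style$n_bins)
  bin <- ubin[match(deg, udeg)]
  setNames(style$palette[bin], igraph::V(graph)$name)
}

#' Incident edges of a node, for neighbour highlighting
#'
#' For a base node: all original-graph edges incident to it. For a cluster
#' node: every hierarchy edge incident to the cluster node (membership and
#' inter-cluster) plus the original edges running from its members to
#' non-members.
#'
#' @param tree A `layout_tree`.
#' @param node Node identifier.
#' @return Two-column character matrix of edge endpoints.
#' @export
highlight_neighbors <- function(tree, node) {
  stopifnot(inherits(tree, "layout_tree"))
  h <- tree$hierarchy$graph
  nms <- igraph::V(h)$name
  if (!(node %in% nms)) stop("unknown node: ", node)
  kind <- igraph::V(h)$kind[match(node, nms)]
  el <- igraph::as_edgelist(h, names = TRUE)
  etype <- if (igraph::ecount(h) > 0) igraph::E(h)$edge_type else character(0)
  if (kind == "base") {
    keep <- etype == "base" & (el[, 1] == node | el[, 2] == node)
    out <- el[keep, , drop = FALSE]
  } else {
    incident <- el[, 1] == node | el[, 2] == node
    members <- names(tree$hierarchy$membership)[
      tree$hierarchy$membership == node]
    lower_type <- if (igraph::V(h)$level[match(node, nms)] == 1L)
      "base" else "intercluster"
    from_members <- etype == lower_type &
      xor(el[, 1] %in% members, el[, 2] %in% members)
    out <- el[incident | from_members, , drop = FALSE]
  }
  colnames(out) <- c("from", "to")
  out
}

#' Hidden internal edges of a cluster
#'
#' The level-below edges among the cluster's direct members: original
#' edges for a level-1 cluster, inter-cluster edges for higher levels.
#'
#' @param tree A `layout_tree`.
#' @param cluster_node Identifier of a cluster node.
#' @return Two-column character matrix of edge endpoints.
#' @export
cluster_internal_edges <- function(tree, cluster_node) {
  stopifnot(inherits(tree, "layout_tree"))
  h <- tree$hierarchy$graph
  nms <- igraph::V(h)$name
  if (!(cluster_node %in% nms)) stop("unknown node: ", cluster_node)
  if (igraph::V(h)$kind[match(cluster_node, nms)] != "cluster") {
    stop("not a cluster node: ", cluster_node)
  }
  members <- names(tree$hierarchy$membership)[
    tree$hierarchy$membership == cluster_node]
  el <- igraph::as_edgelist(h, names = TRUE)
  etype <- igraph::E(h)$edge_type
  keep <- etype != "membership" & el[, 1] %in% members & el[, 2] %in% members
  out <- el[keep, , drop = FALSE]
  colnames(out) <- c("from", "to")
  out
}

#' Render the laid-out tree as an SVG drawing
#'
#' One element per visible node and per tree edge; the hidden root and its
#' incident edges are omitted. Optional highlight edges (e.g. from
#' [highlight_neighbors()] or [cluster_internal_edges()]) are drawn on top
#' in the highlight style. Output is byte-deterministic.
#'
#' @param tree A `layout_tree`.
#' @param layout A `layout_result` covering every tree node.
#' @param style A [style_map()] object.
#' @param path Output SVG path.
#' @param highlights Optional two-column matrix of edges to overlay.
#' @export
render_svg <- function(tree, layout, style = style_map(), path,
                       highlights = NULL) {
  stopifnot(inherits(tree, "layout_tree"),
            inherits(layout, "layout_result"),
            inherits(style, "style_map"))
  pos <- layout$positions
  nodes <- names(tree$parent)
  missing <- setdiff(c(nodes, if (!is.null(highlights)) c(highlights)),
                     rownames(pos))
  if (length(missing)) {
    stop("no position for node(s): ", paste(missing, collapse = ", "))
  }
  h <- tree$hierarchy$graph
  nms <- igraph::V(h)$name
  kind <- setNames(igraph::V(h)$kind, nms)
  level <- setNames(igraph::V(h)$level, nms)
  base_g <- level_subgraph(tree$hierarchy, 0L)
  col <- degree_color(base_g, style)

  fmt <- function(x) sprintf("%.3f", x)
  area <- layout$params$area
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    fmt(area[1]), fmt(area[2]), fmt(area[1]), fmt(area[2])),
    '<rect width="100%" height="100%" fill="white"/>')

  # tree edges (skip edges incident to the hidden root)
  for (v in sort(nodes)) {
    p <- tree$parent[[v]]
    if (p == tree$root) next
    stroke <- if (kind[[v]] == "base" && kind[[p]] == "base")
      style$edge_color else style$membership_color
    lines <- c(lines, sprintf(
      '<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
      fmt(pos[v, 1]), fmt(pos[v, 2]), fmt(pos[p, 1]), fmt(pos[p, 2]),
      stroke))
  }

  if (!is.null(highlights) && NROW(highlights) > 0) {
    hm <- as.matrix(highlights)
    ord <- order(paste(pmin(hm[, 1], hm[, 2]), pmax(hm[, 1], hm[, 2])))
    for (i in ord) {
      lines <- c(lines, sprintf(
        '<line class="highlight" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"/>',
        fmt(pos[hm[i, 1], 1]), fmt(pos[hm[i, 1], 2]),
        fmt(pos[hm[i, 2], 1]), fmt(pos[hm[i, 2], 2]),
        style$highlight_color))
    }
  }

  for (v in sort(nodes)) {
    if (kind[[v]] == "root") next
    x <- pos[v, 1]; y <- pos[v, 2]
    if (kind[[v]] == "base") {
      lines <- c(lines, sprintf(
        '<circle class="node base" cx="%s" cy="%s" r="%s" fill="%s" stroke="black" stroke-width="0.5"><title>%s</title></circle>',
        fmt(x), fmt(y), fmt(style$base_radius),
        if (v %in% names(col)) col[[v]] else style$palette[1], v))
    } else {
      r <- style$base_radius + style$cluster_radius_step * level[[v]]
      lines <- c(lines, sprintf(
        '<path class="node cluster" d="M %s %s L %s %s L %s %s L %s %s Z" fill="#ffd92f" stroke="black" stroke-width="1"><title>%s</title></path>',
        fmt(x - r), fmt(y), fmt(x), fmt(y - r), fmt(x + r), fmt(y),
        fmt(x), fmt(y + r), v))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(NULL)
}
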