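#' @importFrom stats cor quantile rbinom rnorm runif setNames
#' @importFrom utils combn head write.table
NULL

# Canonical vertex attributes every network in this package carries:
#   name  - unique string identifier
#   level - non-negative integer hierarchy level (base nodes are level 0)
#   kind  - "base", "cluster" or "root"
# Edge attribute:
#   edge_type - "base", "intercluster" or "membership"

#' Normalize an igraph object into the package's network representation
#'
#' Ensures the graph is simple (no self-loops or parallel edges) and
#' undirected, that every vertex has a unique string `name`, and that the
#' `level`/`kind` vertex attributes and `edge_type` edge attribute exist
#' with their defaults (level 0, kind "base", edge_type "base").
#'
#' @param graph An igraph object.
#' @return An undirected simple igraph with canonical attributes.
#' @export
as_network_graph <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  # keep the first copy's attributes when collapsing parallel edges;
  # the default combination would silently drop edge_type
  graph <- igraph::simplify(graph, remove.multiple = TRUE,
                            remove.loops = TRUE, edge.attr.comb = "first")
  if (!("name" %in% igraph::vertex_attr_names(graph))) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  nm <- igraph::V(graph)$name
  if (anyNA(nm) || any(!nzchar(nm))) {
    stop("every node needs a non-empty identifier")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate node identifiers: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (!("level" %in% igraph::vertex_attr_names(graph))) {
    igraph::V(graph)$level <- 0L
  }
  igraph::V(graph)$level <- as.integer(igraph::V(graph)$level)
  if (!("kind" %in% igraph::vertex_attr_names(graph))) {
    igraph::V(graph)$kind <- "base"
  }
  if (igraph::ecount(graph) > 0 &&
      !("edge_type" %in% igraph::edge_attr_names(graph))) {
    igraph::E(graph)$edge_type <- "base"
  }
  graph
}

#' Build a network from an explicit node and edge specification
#'
#' Convenience constructor used throughout the package and its tests.
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column matrix or data frame of endpoint identifiers
#'   (may be `NULL` for an edgeless graph).
#' @return A network graph (igraph) with canonical attributes.
#' @export
network_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    missing <- setdiff(unique(c(em)), nodes)
    if (length(missing)) {
      stop("edge endpoints not in node set: ", paste(missing, collapse = ", "))
    }
    g <- igraph::add_edges(g, t(em))
  }
  as_network_graph(g)
}

#' Read an undirected network from a delimited edge list
#'
#' Lines starting with `#` are comments; the first two fields of each line
#' are the edge endpoints (extra fields are ignored, with a one-time warning
#' for a third numeric column since weights are not used). Duplicate edges,
#' reversed duplicates and self-loops are collapsed/dropped; counts are
#' reported via `message()`.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator; `NULL` (default) splits on runs of
#'   spaces/tabs.
#' @return A network graph.
#' @export
read_edge_list <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("empty edge list: ", path)
  split_re <- if (is.null(delimiter)) "[ \t]+" else delimiter
  fields <- strsplit(trimws(lines[idx]), split_re, fixed = !is.null(delimiter))
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("malformed edge-list line ", idx[which(nf < 2)[1]],
         " in ", path, ": fewer than 2 fields")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (any(nf > 2)) {
    third <- vapply(fields[nf > 2], `[[`, "", 3L)
    if (any(!is.na(suppressWarnings(as.numeric(third))))) {
      warning("edge weights in column 3 are ignored; graphs are unweighted")
    }
  }
  loops <- a == b
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  a2 <- a[!loops]; b2 <- b[!loops]
  key <- paste(pmin(a2, b2), pmax(a2, b2))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) collapsed")
  nodes <- unique(c(a, b))
  network_graph(nodes, cbind(a2[!dup], b2[!dup]))
}

#' Write a network to GraphML
#'
#' Emits standard GraphML with vertex keys `level` (int), `kind` (string)
#' and, when positions are supplied, `x`/`y` (double), plus the `edge_type`
#' edge key. The output of [read_graphml()] on the written file reproduces
#' the graph exactly.
#'
#' @param graph A network graph.
#' @param path Output file path.
#' @param positions Optional two-column numeric matrix of coordinates with
#'   node names as rownames.
#' @export
write_graphml <- function(graph, path, positions = NULL) {
  graph <- as_network_graph(graph)
  if (!is.null(positions)) {
    pos <- positions[igraph::V(graph)$name, , drop = FALSE]
    igraph::V(graph)$x <- as.double(pos[, 1])
    igraph::V(graph)$y <- as.double(pos[, 2])
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  e_attrs <- setdiff(igraph::edge_attr_names(graph), character(0))
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="level" for="node" attr.name="level" attr.type="int"/>',
    '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    vapply(e_attrs, function(a) sprintf(
      '  <key id="%s" for="edge" attr.name="%s" attr.type="%s"/>', a, a,
      if (is.numeric(igraph::edge_attr(graph, a))) "double" else "string"),
      "")
  )
  if (!is.null(positions)) {
    out <- c(out,
      '  <key id="x" for="node" attr.name="x" attr.type="double"/>',
      '  <key id="y" for="node" attr.name="y" attr.type="double"/>')
  }
  out <- c(out, '  <graph edgedefault="undirected">')
  nm <- esc(igraph::V(graph)$name)
  node_lines <- sprintf(
    '    <node id="%s"><data key="level">%d</data><data key="kind">%s</data>%s</node>',
    nm, igraph::V(graph)$level, esc(igraph::V(graph)$kind),
    if (is.null(positions)) "" else
      sprintf('<data key="x">%.17g</data><data key="y">%.17g</data>',
              igraph::V(graph)$x, igraph::V(graph)$y))
  out <- c(out, node_lines)
  if (igraph::ecount(graph) > 0) {
    ends <- igraph::as_edgelist(graph, names = TRUE)
    data_parts <- rep("", nrow(ends))
    for (a in e_attrs) {
      vals <- igraph::edge_attr(graph, a)
      vals <- if (is.numeric(vals)) sprintf("%.17g", vals) else esc(vals)
      data_parts <- paste0(data_parts,
                           sprintf('<data key="%s">%s</data>', a, vals))
    }
    out <- c(out, sprintf('    <edge source="%s" target="%s">%s</edge>',
                          esc(ends[, 1]), esc(ends[, 2]), data_parts))
  }
  out <- c(out, "  </graph>", "</graphml>")
  writeLines(out, con)
  invisible(NULL)
}

#' Read a network from GraphML
#'
#' Missing `level` defaults to 0 and missing `kind` to `"base"`. Directed
#' graphs are rejected.
#'
#' @param path Path to a GraphML file.
#' @return A network graph; vertex attributes `x`/`y` are retained when
#'   present so positions round-trip.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("GraphML parse error in ", path,
                                         ": ", conditionMessage(e)))
  if (igraph::is_directed(g)) {
    stop("directed GraphML graphs are not supported: ", path)
  }
  # igraph surfaces GraphML node ids as attribute "id"; promote them to
  # vertex names unless an explicit name key was present
  if ("id" %in% igraph::vertex_attr_names(g)) {
    if (!("name" %in% igraph::vertex_attr_names(g))) {
      igraph::V(g)$name <- igraph::V(g)$id
    }
    g <- igraph::delete_vertex_attr(g, "id")
  }
  as_network_graph(g)
}

#' Degree of a node in a network
#'
#' @param graph A network graph.
#' @param node Node identifier.
#' @return Number of incident edges.
#' @export
node_degree <- function(graph, node) {
  graph <- as_network_graph(graph)
  if (!(node %in% igraph::V(graph)$name)) stop("unknown node: ", node)
  as.integer(igraph::degree(graph, node))
}

# Canonical "u|v" edge keys with endpoints sorted, for set algebra on edges.
edge_keys <- function(graph, names_matrix = NULL) {
  em <- if (is.null(names_matrix)) igraph::as_edgelist(graph, names = TRUE)
        else names_matrix
  if (NROW(em) == 0) return(character(0))
  paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]), sep = "|")
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
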