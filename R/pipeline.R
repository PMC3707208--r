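# End-to-end pipeline: read a network (or build one from expression
# data), cluster it into a multilevel hierarchy, transform to a tree, lay
# it out, render the SVG and write a run manifest. One global seed derives
# every stage seed, so a config reproduces its outputs byte for byte.

#' Pipeline configuration
#'
#' @param input Path to the input file, or an in-memory network graph /
#'   expression matrix.
#' @param format One of `"edgelist"`, `"graphml"`, `"expression"` or
#'   `"auto"` (by file extension; in-memory objects are detected by type).
#' @param out_dir Output directory (created if missing).
#' @param gamma Gamma schedule values (see [gamma_schedule()]).
#' @param min_size,restarts,rcl_alpha Cluster search settings (see
#'   [cluster_search_params()]).
#' @param threshold Correlation threshold, used only for expression input.
#' @param layout A [layout_params()] object (its seed is overridden by the
#'   derived stage seed).
#' @param style A [style_map()] object.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input, format = "auto", out_dir = ".",
                            gamma = c(0.5, 0.7), min_size = 3L,
                            restarts = 20L, rcl_alpha = 0.2,
                            threshold = 0.72,
                            layout = layout_params(), style = style_map(),
                            seed = 1L) {
  format <- match.arg(format, c("auto", "edgelist", "graphml", "expression"))
  structure(list(input = input, format = format, out_dir = out_dir,
                 gamma = gamma, min_size = as.integer(min_size),
                 restarts = as.integer(restarts), rcl_alpha = rcl_alpha,
                 threshold = threshold, layout = layout, style = style,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_input <- function(config) {
  inp <- config$input
  if (igraph::is_igraph(inp)) {
    return(list(graph = as_network_graph(inp), source = "graph object"))
  }
  if (is.matrix(inp)) {
    return(list(graph = correlation_network(inp, config$threshold),
                source = "expression object"))
  }
  stopifnot(is.character(inp), length(inp) == 1)
  if (!file.exists(inp)) stop("input not found: ", inp)
  fmt <- config$format
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(inp)),
                  graphml = "graphml",
                  tsv = , csv = , txt = , edges = "edgelist",
                  stop("cannot infer format of ", inp,
                       "; set format explicitly"))
  }
  g <- switch(fmt,
    edgelist = read_edge_list(inp,
      delimiter = if (tolower(tools::file_ext(inp)) == "csv") "," else NULL),
    graphml = read_graphml(inp),
    expression = correlation_network(read_expression_matrix(inp),
                                     config$threshold))
  list(graph = g, source = inp)
}

# Fixed per-stage offsets keep stage seeds distinct yet reproducible.
stage_seed <- function(seed, stage) {
  seed + c(cluster = 11L, tree = 23L, layout = 37L)[[stage]]
}

#' Run the full pipeline
#'
#' Reads the input, builds the multilevel hierarchy, transforms it to a
#' tree, computes the layout, renders the SVG, and writes clusters TSV,
#' hierarchy/tree GraphML, positions JSON and a JSON manifest (parameters,
#' seed, level count, per-level summaries, output paths). Identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c(clusters = "clusters.tsv",
                       hierarchy = "hierarchy.graphml",
                       tree = "tree.graphml",
                       parents = "tree_parents.tsv",
                       positions = "positions.json",
                       svg = "network.svg",
                       manifest = "manifest.json"))
  names(paths) <- c("clusters", "hierarchy", "tree", "parents",
                    "positions", "svg", "manifest")

  stage <- "input"
  result <- tryCatch({
    inp <- resolve_input(config)
    graph <- inp$graph

    stage <- "clustering"
    params <- cluster_search_params(gamma = config$gamma[1],
                                    min_size = config$min_size,
                                    restarts = config$restarts,
                                    rcl_alpha = config$rcl_alpha,
                                    seed = stage_seed(config$seed, "cluster"))
    hier <- create_multilevel_clusters(graph, gamma_schedule(config$gamma),
                                       params)
    write_clusters_tsv(hier$clusters, paths[["clusters"]])
    write_hierarchy_graphml(hier, paths[["hierarchy"]])

    stage <- "tree"
    tree <- tree_transformation(hier, seed = stage_seed(config$seed, "tree"))
    write_parent_map_tsv(tree, paths[["parents"]])

    stage <- "layout"
    lp <- config$layout
    lp$seed <- stage_seed(config$seed, "layout")
    lay <- force_layout(tree, lp)
    write_positions_json(lay, paths[["positions"]])
    write_tree_graphml(tree, paths[["tree"]], positions = lay$positions)

    stage <- "render"
    render_svg(tree, lay, config$style, paths[["svg"]])

    levels_summary <- hierarchy_summary(hier)
    per_level_clusters <- table(factor(
      vapply(hier$clusters, `[[`, 0L, "level"),
      levels = as.character(seq_len(max(1L, hier$n_levels)))))
    manifest <- list(
      input = inp$source,
      seed = config$seed,
      parameters = list(gamma = config$gamma, min_size = config$min_size,
                        restarts = config$restarts,
                        rcl_alpha = config$rcl_alpha),
      n_levels = hier$n_levels,
      n_clusters = length(hier$clusters),
      clusters_per_level = as.list(setNames(as.integer(per_level_clusters),
                                            paste0("level_",
                                                   names(per_level_clusters)))),
      levels = levels_summary,
      n_orphans = length(tree$orphans),
      layout = list(iterations = lay$iterations_run,
                    converged = lay$converged),
      # relative names so a manifest depends only on config + seed
      outputs = as.list(setNames(basename(unname(paths)), names(paths))))
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
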