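# Hierarchy-aware force-directed layout.
#
# The tree is initialized on concentric circles (root at the centre, depth
# d on circle d) with angular segments handed down recursively from parent
# to children, then relaxed with a spring model: Hooke attraction along
# tree edges toward a level-dependent target length, and short-range
# pairwise repulsion that is switched off beyond a cutoff distance derived
# from the drawing area (which also keeps disconnected pieces from
# drifting apart). Oscillations are suppressed by averaging each node's
# raw position over a sliding window of recent iterations.

#' Layout parameters
#'
#' @param area Drawing area `c(width, height)` in abstract units.
#' @param base_edge_length Target length of the deepest-level edges.
#' @param level_factor Per-level length multiplier (> 1), so edges between
#'   higher hierarchy levels are drawn longer.
#' @param repulsion_cutoff_fraction Repulsion acts only within
#'   `fraction * min(width, height)`.
#' @param damping_window Number of recent raw positions averaged per node.
#' @param max_iterations Iteration cap.
#' @param convergence_tol Stop once the largest per-iteration displacement
#'   falls below this.
#' @param seed Seed for the tiny symmetry-breaking jitter.
#' @return A `layout_params` object.
#' @export
layout_params <- function(area = c(1000, 1000), base_edge_length = 30,
                          level_factor = 1.6,
                          repulsion_cutoff_fraction = 0.25,
                          damping_window = 3L, max_iterations = 300L,
                          convergence_tol = 0.05, seed = 1L) {
  stopifnot(length(area) == 2, all(area > 0), base_edge_length > 0,
            repulsion_cutoff_fraction > 0, repulsion_cutoff_fraction <= 1,
            damping_window >= 1, max_iterations >= 1, convergence_tol > 0)
  if (level_factor <= 1) {
    stop("level_factor must be > 1 so higher-level edges are longer")
  }
  structure(list(area = as.double(area),
                 base_edge_length = as.double(base_edge_length),
                 level_factor = as.double(level_factor),
                 repulsion_cutoff_fraction =
                   as.double(repulsion_cutoff_fraction),
                 damping_window = as.integer(damping_window),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = as.double(convergence_tol),
                 seed = as.integer(seed)),
            class = "layout_params")
}

#' Target length of an edge at a hierarchy level
#'
#' `base_edge_length * level_factor^edge_level`. The level of a tree edge
#' is the hierarchy level of its deeper endpoint (for a membership edge
#' from a level-L cluster to a member, the member's level L-1), so
#' root-to-top-cluster edges take the top level.
#'
#' @param edge_level Non-negative hierarchy level.
#' @param params A [layout_params()] object.
#' @return Positive target length.
#' @export
edge_target_length <- function(edge_level, params) {
  stopifnot(inherits(params, "layout_params"))
  if (any(edge_level < 0)) stop("edge level must be non-negative")
  params$base_edge_length * params$level_factor^edge_level
}

tree_children <- function(tree) {
  kids <- split(names(tree$parent), tree$parent)
  lapply(kids, sort)
}

#' Concentric-circle initial positions
#'
#' Root at the area centre; a node at depth d sits on circle d, placed at
#' the bisector of its angular segment. Each node's segment is a fraction
#' of its parent's, split among siblings proportionally to their subtree
#' leaf counts so large subtrees get room. A tiny seeded jitter breaks
#' exact overlaps on symmetric trees.
#'
#' @param tree A `layout_tree`.
#' @param params A [layout_params()] object.
#' @return Numeric matrix (nodes x 2) of coordinates, rownames = node
#'   names (root included).
#' @export
initial_positions <- function(tree, params) {
  stopifnot(inherits(tree, "layout_tree"), inherits(params, "layout_params"))
  nodes <- c(tree$root, names(tree$parent))
  n <- length(nodes)
  centre <- params$area / 2
  pos <- matrix(0, n, 2, dimnames = list(nodes, c("x", "y")))
  pos[tree$root, ] <- centre
  if (n == 1) return(pos)

  height <- max(tree$depth)
  ring <- min(params$area) / 2 / max(height, 1) * 0.9
  kids <- tree_children(tree)

  leaf_count <- setNames(rep(1L, n), nodes)
  for (v in names(sort(tree$depth[nodes], decreasing = TRUE))) {
    ch <- kids[[v]]
    if (!is.null(ch)) leaf_count[v] <- sum(leaf_count[ch])
  }

  # walk down assigning [lo, hi) angular segments
  seg_lo <- setNames(rep(0, n), nodes)
  seg_hi <- setNames(rep(2 * pi, n), nodes)
  ord <- names(sort(tree$depth[nodes]))
  for (v in ord) {
    ch <- kids[[v]]
    if (is.null(ch)) next
    lo <- seg_lo[v]; width <- seg_hi[v] - seg_lo[v]
    w <- leaf_count[ch] / sum(leaf_count[ch])
    br <- lo + width * cumsum(c(0, w))
    seg_lo[ch] <- br[-length(br)]
    seg_hi[ch] <- br[-1]
  }
  non_root <- setdiff(nodes, tree$root)
  ang <- (seg_lo[non_root] + seg_hi[non_root]) / 2
  r <- tree$depth[non_root] * ring
  pos[non_root, 1] <- centre[1] + r * cos(ang)
  pos[non_root, 2] <- centre[2] + r * sin(ang)
  jit <- with_seed(params$seed,
                   matrix(runif(2 * n, -1, 1), n, 2)) *
    1e-6 * params$base_edge_length
  pos <- pos + jit
  clip_to_area(pos, params$area)
}

clip_to_area <- function(pos, area) {
  pos[, 1] <- pmin(pmax(pos[, 1], 0), area[1])
  pos[, 2] <- pmin(pmax(pos[, 2], 0), area[2])
  pos
}

# Hierarchy level of each tree edge = level attribute of the child node.
tree_edge_levels <- function(tree) {
  ch <- names(tree$parent)
  lv <- igraph::V(tree$graph)$level
  names(lv) <- igraph::V(tree$graph)$name
  lv[ch]
}

#' Force-directed layout of a transformed tree
#'
#' Iterates spring attraction along tree edges toward their
#' level-dependent target lengths plus cutoff-limited repulsion, with
#' sliding-window position averaging; deterministic for fixed parameters.
#' Spring rest lengths are adjusted so an isolated edge equilibrates at
#' exactly its target length despite the residual repulsion between its
#' endpoints.
#'
#' @param tree A `layout_tree`.
#' @param params A [layout_params()] object.
#' @return A `layout_result` with `positions` (matrix), `iterations_run`,
#'   `converged` and `params`.
#' @export
force_layout <- function(tree, params) {
  stopifnot(inherits(tree, "layout_tree"), inherits(params, "layout_params"))
  pos <- initial_positions(tree, params)
  nodes <- rownames(pos)
  n <- nrow(pos)
  if (n <= 1) {
    return(structure(list(positions = pos, iterations_run = 0L,
                          converged = TRUE, params = params),
                     class = "layout_result"))
  }

  ei <- match(names(tree$parent), nodes)
  ej <- match(unname(tree$parent), nodes)
  target <- edge_target_length(tree_edge_levels(tree), params)
  k_spring <- 0.08
  q_rep <- (0.35 * params$base_edge_length)^2   # repulsion strength
  rest <- pmax(target - q_rep / target, 0.1 * target)
  cutoff <- params$repulsion_cutoff_fraction * min(params$area)
  step_max <- 0.5 * params$base_edge_length     # displacement clamp
  eps <- 1e-9

  history <- list()
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    disp <- matrix(0, n, 2)

    # springs along tree edges
    dx <- pos[ei, 1] - pos[ej, 1]
    dy <- pos[ei, 2] - pos[ej, 2]
    d <- sqrt(dx^2 + dy^2) + eps
    f <- k_spring * (d - rest)                  # >0 pulls together
    fx <- f * dx / d; fy <- f * dy / d
    disp[, 1] <- disp[, 1] - rowsum_at(fx, ei, n) + rowsum_at(fx, ej, n)
    disp[, 2] <- disp[, 2] - rowsum_at(fy, ei, n) + rowsum_at(fy, ej, n)

    # pairwise repulsion within the cutoff
    ddx <- outer(pos[, 1], pos[, 1], "-")
    ddy <- outer(pos[, 2], pos[, 2], "-")
    dd <- sqrt(ddx^2 + ddy^2)
    w <- ifelse(dd > eps & dd < cutoff, q_rep / pmax(dd, eps)^2, 0)
    diag(w) <- 0
    disp[, 1] <- disp[, 1] + rowSums(w * ddx / pmax(dd, eps))
    disp[, 2] <- disp[, 2] + rowSums(w * ddy / pmax(dd, eps))

    # clamp step, update, average over the damping window, clip
    step <- sqrt(disp[, 1]^2 + disp[, 2]^2)
    scale <- ifelse(step > step_max, step_max / step, 1)
    raw <- pos + disp * scale
    history <- c(history, list(raw))
    if (length(history) > params$damping_window) {
      history <- history[-1]
    }
    new_pos <- Reduce(`+`, history) / length(history)
    new_pos <- clip_to_area(new_pos, params$area)
    moved <- max(sqrt((new_pos[, 1] - pos[, 1])^2 +
                        (new_pos[, 2] - pos[, 2])^2))
    pos <- new_pos
    if (moved < params$convergence_tol) { converged <- TRUE; break }
  }

  structure(list(positions = pos, iterations_run = iter,
                 converged = converged, params = params),
            class = "layout_result")
}

rowsum_at <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.layout_result <- function(x, ...) {
  cat(sprintf("layout: %d nodes, %d iteration(s), converged: %s\n",
              nrow(x$positions), x$iterations_run, x$converged))
  invisible(x)
}

#' Write node positions as JSON
#'
#' @param layout A `layout_result`.
#' @param path Output path.
#' @export
write_positions_json <- function(layout, path) {
  stopifnot(inherits(layout, "layout_result"))
  pos <- layout$positions
  obj <- lapply(seq_len(nrow(pos)), function(i) round(unname(pos[i, ]), 6))
  names(obj) <- rownames(pos)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}
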