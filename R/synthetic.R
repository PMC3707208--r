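# Seeded generators for benchmark structures: planted-partition graphs
# (dense blocks in a sparse background), cliques joined by a matching (the
# structure a minimum-spanning-tree layout collapses), preferential-
# attachment graphs with skewed degree distributions, and block-structured
# expression matrices for correlation-network tests. All generators are
# pure functions of their arguments and seed.

#' Planted-partition random graph
#'
#' Bernoulli edges with probability `p_in` within blocks and `p_out`
#' between blocks; block membership is returned as ground truth.
#'
#' @param n_blocks Number of blocks.
#' @param block_size Nodes per block.
#' @param p_in,p_out Edge probabilities within / between blocks.
#' @param seed Integer seed.
#' @return List with `graph` and `blocks` (named character: node -> block
#'   label).
#' @export
planted_partition <- function(n_blocks, block_size, p_in, p_out, seed = 1L) {
  stopifnot(n_blocks >= 1, block_size >= 2,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  if (p_in <= p_out) {
    warning("p_in <= p_out: planted structure is not denser than background")
  }
  n <- n_blocks * block_size
  nodes <- sprintf("v%03d", seq_len(n))
  block <- rep(seq_len(n_blocks), each = block_size)
  pairs <- t(combn(n, 2))
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  p <- ifelse(same, p_in, p_out)
  draw <- with_seed(seed, runif(nrow(pairs)) < p)
  g <- network_graph(nodes, cbind(nodes[pairs[draw, 1]],
                                  nodes[pairs[draw, 2]]))
  list(graph = g, blocks = setNames(sprintf("B%d", block), nodes))
}

#' Cliques joined by a perfect matching
#'
#' Disjoint cliques of equal size whose consecutive pairs are joined by a
#' perfect matching (node i of one clique to node i of the next) — the
#' pathological case where a minimum-spanning-tree preprocessing collapses
#' one clique onto a single edge.
#'
#' @param clique_size Size of each clique (>= 3).
#' @param n_cliques Number of cliques (default 2).
#' @param seed Unused; accepted for generator-interface uniformity.
#' @return A network graph with `n_cliques * clique_size` nodes.
#' @export
cliques_joined_by_matching <- function(clique_size, n_cliques = 2L,
                                       seed = 1L) {
  stopifnot(clique_size >= 3, n_cliques >= 2)
  nodes <- c(outer(seq_len(clique_size), seq_len(n_cliques),
                   function(i, q) sprintf("q%d_%d", q, i)))
  edges <- NULL
  for (q in seq_len(n_cliques)) {
    ids <- sprintf("q%d_%d", q, seq_len(clique_size))
    pr <- t(combn(ids, 2))
    edges <- rbind(edges, pr)
    if (q < n_cliques) {
      nxt <- sprintf("q%d_%d", q + 1L, seq_len(clique_size))
      edges <- rbind(edges, cbind(ids, nxt))
    }
  }
  network_graph(nodes, edges)
}

#' Preferential-attachment (scale-free) graph
#'
#' Convention: the seed graph is a star on `m + 1` nodes (node 1 the hub);
#' each subsequent node attaches to `m` distinct existing nodes drawn with
#' probability proportional to current degree. Total edge count is
#' therefore exactly `m * (n - m)`.
#'
#' @param n Number of nodes.
#' @param m Edges added per new node (`1 <= m < n`).
#' @param seed Integer seed.
#' @return A network graph.
#' @export
scale_free_graph <- function(n, m, seed = 1L) {
  stopifnot(m >= 1, m < n)
  nodes <- sprintf("s%04d", seq_len(n))
  deg <- integer(n)
  edges <- matrix(integer(0), ncol = 2)
  hub_edges <- cbind(1L, seq_len(m) + 1L)
  deg[1] <- m
  deg[2:(m + 1)] <- 1L
  edges <- rbind(edges, hub_edges)
  if (n > m + 1L) {
    with_seed(seed, {
      for (v in (m + 2L):n) {
        existing <- seq_len(v - 1L)
        targets <- sample(existing, m, prob = deg[existing])
        edges <- rbind(edges, cbind(v, targets))
        deg[targets] <- deg[targets] + 1L
        deg[v] <- m
      }
    })
  }
  network_graph(nodes, cbind(nodes[edges[, 1]], nodes[edges[, 2]]))
}

#' Block-structured synthetic expression matrix
#'
#' Each block of genes is driven by one latent factor (standard normal
#' across samples) plus independent Gaussian noise, yielding high
#' within-block and near-zero between-block correlations.
#'
#' @param n_blocks Number of co-expressed gene blocks.
#' @param genes_per_block Genes per block.
#' @param n_samples Number of samples (>= 3).
#' @param noise_sd Noise standard deviation (0 gives within-block r = 1).
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples) and `blocks` (named
#'   character: gene -> block label).
#' @export
synthetic_expression <- function(n_blocks, genes_per_block, n_samples,
                                 noise_sd = 0.1, seed = 1L) {
  stopifnot(n_blocks >= 1, genes_per_block >= 1, n_samples >= 3,
            noise_sd >= 0)
  genes <- c(outer(seq_len(genes_per_block), seq_len(n_blocks),
                   function(i, b) sprintf("g%d_%d", b, i)))
  m <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      f <- rnorm(n_samples)
      t(vapply(seq_len(genes_per_block), function(i)
        f + rnorm(n_samples, sd = noise_sd), numeric(n_samples)))
    }))
  })
  rownames(m) <- genes
  colnames(m) <- sprintf("sample%d", seq_len(n_samples))
  block <- rep(seq_len(n_blocks), each = genes_per_block)
  list(matrix = m, blocks = setNames(sprintf("B%d", block), genes))
}

#' Seeded Erdos-Renyi G(n, p) graph
#'
#' Small utility generator used by the package's own benchmarks and tests.
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return A network graph.
#' @export
random_gnp <- function(n, p, seed = 1L) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  nodes <- sprintf("n%03d", seq_len(n))
  if (n == 1) return(network_graph(nodes))
  pairs <- t(combn(n, 2))
  draw <- with_seed(seed, runif(nrow(pairs)) < p)
  network_graph(nodes, cbind(nodes[pairs[draw, 1]], nodes[pairs[draw, 2]]))
}
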