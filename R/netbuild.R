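# Gene co-expression network construction by correlation thresholding.

#' Read an expression matrix from TSV
#'
#' Genes in rows (first column gene identifiers), a header row of sample
#' identifiers.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, rownames genes, colnames samples.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  validate_expression(m)
  m
}

validate_expression <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression input must be a matrix with gene rownames and sample colnames")
  }
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Build a correlation network from an expression matrix
#'
#' Computes all pairwise Pearson correlations between genes (rows) and
#' connects two genes when their correlation exceeds the threshold
#' (strictly, since an edge marks correlation *above* the cutoff).
#' Zero-variance genes have undefined correlations and never gain edges;
#' their count is reported via `message()`.
#'
#' @param matrix Numeric expression matrix, genes x samples.
#' @param threshold Correlation threshold in `(-1, 1)`.
#' @param keep_isolated Keep genes without any edge as isolated nodes
#'   (default drops them).
#' @param use_absolute Threshold `|r|` instead of `r` (off by default:
#'   strong negative correlation does not create an edge).
#' @param strict Use `r > threshold` (default) rather than `>=`.
#' @return A network graph whose nodes are genes.
#' @export
correlation_network <- function(matrix, threshold, keep_isolated = FALSE,
                                use_absolute = FALSE, strict = TRUE) {
  validate_expression(matrix)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= -1 || threshold >= 1) {
    stop("threshold must be a single number in (-1, 1)")
  }
  if (ncol(matrix) < 3) stop("need at least 3 samples")
  if (nrow(matrix) < 2) stop("need at least 2 genes")
  sds <- apply(matrix, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    message(sum(flat), " zero-variance gene(s) excluded from correlations")
  }
  genes <- rownames(matrix)
  active <- genes[!flat]
  edges <- NULL
  if (length(active) >= 2) {
    r <- cor(t(matrix[active, , drop = FALSE]))
    if (use_absolute) r <- abs(r)
    hit <- if (strict) r > threshold else r >= threshold
    hit[lower.tri(hit, diag = TRUE)] <- FALSE
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) edges <- cbind(active[idx[, 1]], active[idx[, 2]])
  }
  nodes <- if (keep_isolated) genes else unique(c(edges))
  if (is.null(nodes)) nodes <- character(0)
  network_graph(nodes, edges)
}

#' Check that lowering the threshold never removes edges
#'
#' Property helper: the edge set at a higher threshold is always a subset
#' of the edge set at a lower threshold, so the returned value is `TRUE`
#' for any valid input.
#'
#' @inheritParams correlation_network
#' @param t1,t2 Thresholds with `t1 < t2`.
#' @return `TRUE` iff the network at `t1` has at least as many edges as at
#'   `t2` and contains all of its edges.
#' @export
edge_count_monotonicity <- function(matrix, t1, t2) {
  if (t1 >= t2) stop("expected t1 < t2")
  g1 <- correlation_network(matrix, t1)
  g2 <- correlation_network(matrix, t2)
  k1 <- edge_keys(g1); k2 <- edge_keys(g2)
  all(k2 %in% k1) && length(k1) >= length(k2)
}
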