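#' Build the gene relationship graph
#'
#' Assembles the undirected weighted gene graph G = (V, E) from a dataset and
#' an interaction edge list. Nodes are the dataset's genes (sorted for
#' reproducible matrix order); edges are restricted to pairs where both genes
#' are present. Each node's initial state vector h0 is the gene's expression
#' profile across samples, z-scored per gene by default since downstream
#' similarity kernels are scale-sensitive.
#'
#' @param ds an [expression_dataset()].
#' @param edges a [weighted_edge_list()].
#' @param keep_isolated keep genes without any retained edge as isolated
#'   nodes (default TRUE; their neighborhood aggregate is the zero vector).
#' @param scale_states z-score each gene's profile before use as h0.
#' @return A `gene_graph`: list with `nodes` (sorted gene IDs), `A` (sparse
#'   symmetric weighted adjacency, zero diagonal), `H0` (nodes x samples
#'   initial-state matrix).
#' @export
build_gene_graph <- function(ds, edges, keep_isolated = TRUE, scale_states = TRUE) {
  genes <- colnames(ds$X)
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  e <- edges[keep, , drop = FALSE]
  if (!nrow(e)) {
    overlap <- length(intersect(unique(c(edges$gene_a, edges$gene_b)), genes))
    stop("construction error: no edge joins two dataset genes (ID overlap: ",
         overlap, " genes)")
  }
  nodes <- if (keep_isolated) sort(genes) else sort(unique(c(e$gene_a, e$gene_b)))
  m <- length(nodes)
  ia <- match(e$gene_a, nodes)
  ib <- match(e$gene_b, nodes)
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = rep(e$weight, 2L), dims = c(m, m),
                            dimnames = list(nodes, nodes))
  Xn <- ds$X[, nodes, drop = FALSE]
  if (scale_states) Xn <- zscore_cols(Xn)
  H0 <- t(Xn)  # nodes x samples
  structure(list(nodes = nodes, A = A, H0 = H0), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d edges, state dim %d\n",
              length(x$nodes), graph_edge_count(x), ncol(x$H0)))
  invisible(x)
}

#' Number of undirected edges in a gene graph
#' @param g a `gene_graph`.
#' @return integer edge count.
#' @export
graph_edge_count <- function(g) {
  length(Matrix::which(Matrix::triu(g$A, k = 1) != 0))
}

# Edge list (i < j index pairs) of a gene_graph.
graph_edge_indices <- function(g) {
  Au <- Matrix::triu(g$A, k = 1)
  idx <- Matrix::which(Au != 0, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# Neighbor index list per node.
graph_neighbors <- function(g) {
  m <- length(g$nodes)
  idx <- Matrix::which(g$A != 0, arr.ind = TRUE)
  split(idx[, 2L], factor(idx[, 1L], levels = seq_len(m)))
}

# Row-normalized adjacency: rows sum to 1 over the neighborhood (weighted
# mean aggregation); isolated nodes keep an all-zero row.
aggregation_operator <- function(g) {
  rs <- Matrix::rowSums(g$A)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  Matrix::Diagonal(x = inv) %*% g$A
}

#' Convert a gene graph back to a weighted edge list
#' @param g a `gene_graph`.
#' @return A [weighted_edge_list()].
#' @export
graph_to_edge_list <- function(g) {
  idx <- graph_edge_indices(g)
  weighted_edge_list(g$nodes[idx[, 1L]], g$nodes[idx[, 2L]],
                     g$A[idx])
}
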