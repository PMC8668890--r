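# Fixtures built in code; no files on disk.

# A tiny two-class dataset with named genes.
tiny_dataset <- function(n = 10, genes = c("a", "b", "c"), seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(genes)), n, length(genes),
                dimnames = list(paste0("S", seq_len(n)), genes))
  })
  expression_dataset(X, rep_len(c(0L, 1L), n))
}

# Build a gene_graph directly from explicit states and edges (no scaling),
# for hand-computed oracles.
graph_from_parts <- function(states, edges_df) {
  genes <- rownames(states)
  n <- ncol(states)
  X <- t(states)
  rownames(X) <- paste0("S", seq_len(n))
  y <- rep_len(c(0L, 1L), n)
  ds <- expression_dataset(X, y)
  el <- weighted_edge_list(edges_df$a, edges_df$b, edges_df$w)
  build_gene_graph(ds, el, keep_isolated = TRUE, scale_states = FALSE)
}

# Identity-like gnn_params: one layer, W = identity on the concatenation,
# identity activation, so update is concat + L2 normalization.
identity_params <- function(input_dim) {
  p <- gnn_params(input_dim = input_dim, n_layers = 1,
                  hidden_dim = 2L * input_dim, activation = "identity", seed = 1)
  p$weights[[1]] <- diag(2L * input_dim)
  p
}

# Minimal link_sample_set for loss oracles.
fake_samples <- function(pos, neg_list, nodes) {
  structure(list(pos = pos, neg = neg_list, gamma = 1L, seed = 1L,
                 nodes = nodes),
            class = "link_sample_set")
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Expected MRR of a uniform random ranker among c candidates: H_c / c.
random_mrr <- function(c) sum(1 / seq_len(c)) / c

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
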