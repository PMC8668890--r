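#' Gaussian similarity matrix of node embeddings
#'
#' Dense kernel `w(a, b) = exp(-||e_a - e_b||^2 / (2 Omega^2))` over all node
#' pairs; `Omega` ("neighborhood width") controls how fast similarity decays
#' with embedding distance. `Omega = "auto"` uses the median nonzero pairwise
#' distance.
#'
#' @param emb embedding matrix, rows named by node.
#' @param omega positive bandwidth or `"auto"`.
#' @return A `similarity_matrix`: list with `W` (symmetric, unit diagonal,
#'   entries in (0, 1]), `nodes`, `omega`.
#' @export
gaussian_similarity <- function(emb, omega = "auto") {
  if (nrow(emb) < 2L) stop("need at least two nodes")
  D2 <- as.matrix(stats::dist(emb))^2
  if (identical(omega, "auto")) {
    d <- sqrt(D2[upper.tri(D2)])
    omega <- stats::median(d[d > 0])
    if (!is.finite(omega) || omega == 0) omega <- 1
  }
  if (!is.numeric(omega) || omega <= 0) stop("parameter error: omega must be positive")
  W <- exp(-D2 / (2 * omega^2))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(rownames(emb), rownames(emb))
  structure(list(W = W, nodes = rownames(emb), omega = omega),
            class = "similarity_matrix")
}

#' Symmetric normalized graph Laplacian
#'
#' `L = D^{-1/2} (D - W) D^{-1/2}` with `D = diag(rowSums(W))`; symmetric
#' with eigenvalues in `[0, 2]` and smallest eigenvalue 0 (eigenvector
#' `D^{1/2} 1`).
#'
#' @param sim a [gaussian_similarity()] result, or a symmetric nonnegative
#'   matrix with positive row sums.
#' @return symmetric numeric matrix.
#' @export
normalized_laplacian <- function(sim) {
  W <- if (inherits(sim, "similarity_matrix")) sim$W else as.matrix(sim)
  d <- rowSums(W)
  if (any(d <= 0)) stop("numeric error: zero row sum in similarity matrix")
  inv_sqrt <- 1 / sqrt(d)
  L <- -W * tcrossprod(inv_sqrt)
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

#' Spectral embedding from the normalized Laplacian
#'
#' Takes the eigenvectors of the `mu` smallest eigenvalues of
#' [normalized_laplacian()] as columns of the `zeta x mu` matrix U; each
#' column's sign is fixed so its largest-magnitude entry is positive
#' (deterministic across eigen-solvers), and rows are optionally rescaled to
#' unit norm (the usual step for the symmetric normalized Laplacian).
#'
#' @param sim a [gaussian_similarity()] result.
#' @param mu number of clusters / embedding dimension, `1 <= mu <= zeta`.
#' @param row_normalize rescale each nonzero row of U to unit norm.
#' @return A `spectral_embedding`: list with `values` (mu smallest
#'   eigenvalues ascending), `U` (`zeta x mu`, rows named by node),
#'   `row_normalized`.
#' @export
spectral_embed <- function(sim, mu, row_normalize = TRUE) {
  zeta <- length(sim$nodes)
  if (mu < 1 || mu > zeta) stop("parameter error: mu must be in [1, ", zeta, "]")
  L <- normalized_laplacian(sim)
  es <- eigen(L, symmetric = TRUE)
  ord <- seq(zeta, zeta - mu + 1L)  # eigen returns descending values
  vals <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(U))) {
    i_max <- which.max(abs(U[, k]))
    if (U[i_max, k] < 0) U[, k] <- -U[, k]
  }
  if (row_normalize) U <- normalize_rows(U)
  rownames(U) <- sim$nodes
  structure(list(values = vals, U = U, row_normalized = row_normalize),
            class = "spectral_embedding")
}

# k-means++ center selection on rows of X.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = p)
    d2_new <- rowSums((X - matrix(X[centers[j + 1L], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  X[centers, , drop = FALSE]
}

#' Cluster the rows of a spectral embedding
#'
#' k-means on the rows of U with k-means++ initialization, best of
#' `restarts` runs by total within-cluster sum of squares; deterministic per
#' seed. If a run ends with an empty cluster it is repaired by splitting the
#' largest cluster (farthest point becomes a new center) and logged.
#'
#' @param se a [spectral_embed()] result.
#' @param mu number of clusters (must equal `ncol(se$U)` in normal use).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (>= 1).
#' @return integer cluster labels in `0..mu-1`, named by node.
#' @export
cluster_rows <- function(se, mu = ncol(se$U), seed = 1, restarts = 10) {
  if (restarts < 1) stop("restarts must be >= 1")
  U <- se$U
  n <- nrow(U)
  if (mu < 1 || mu > n) stop("parameter error: mu must be in [1, ", n, "]")
  if (mu == 1L) return(stats::setNames(rep(0L, n), rownames(U)))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      C0 <- kmeanspp_centers(U, mu)
      # jitter exact-duplicate centers so stats::kmeans accepts them
      dup <- duplicated(round(C0, 12))
      if (any(dup)) C0[dup, ] <- C0[dup, , drop = FALSE] +
          stats::rnorm(sum(dup) * ncol(C0), sd = 1e-8)
      km <- tryCatch(
        stats::kmeans(U, centers = C0, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL,
        warning = function(w) suppressWarnings(
          stats::kmeans(U, centers = C0, iter.max = 200, algorithm = "Lloyd")))
      if (is.null(km)) next
      if (length(unique(km$cluster)) < mu) km <- repair_empty_clusters(U, km, mu)
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed on all restarts")
  stats::setNames(as.integer(best$cluster) - 1L, rownames(U))
}

repair_empty_clusters <- function(U, km, mu) {
  labels <- km$cluster
  present <- sort(unique(labels))
  missing <- setdiff(seq_len(mu), present)
  for (mlab in missing) {
    sizes <- table(labels)
    big <- as.integer(names(sizes)[which.max(sizes)])
    idx <- which(labels == big)
    ctr <- colMeans(U[idx, , drop = FALSE])
    far <- idx[which.max(rowSums((U[idx, , drop = FALSE] -
                                    matrix(ctr, length(idx), ncol(U), byrow = TRUE))^2))]
    labels[far] <- mlab
  }
  gnnsc_log("cluster_rows: repaired %d empty cluster(s)", length(missing))
  centers <- do.call(rbind, lapply(seq_len(mu), function(k)
    colMeans(U[labels == k, , drop = FALSE])))
  wss <- sum(vapply(seq_len(mu), function(k) {
    rowsq <- U[labels == k, , drop = FALSE] -
      matrix(centers[k, ], sum(labels == k), ncol(U), byrow = TRUE)
    sum(rowsq^2)
  }, 0))
  list(cluster = labels, tot.withinss = wss)
}

#' Partition a graph by cluster labels
#'
#' Induces one subgraph per cluster; edges crossing clusters are dropped
#' (counted and logged). Non-contiguous label sets are relabeled to
#' `0..mu-1` preserving order.
#'
#' @param gstar a `gene_graph` (typically the augmented graph G*).
#' @param labels integer labels named by node, covering all nodes of `gstar`.
#' @return A `cluster_assignment`: list with `labels` (canonical, named),
#'   `mu`, `clusters` (list of node-ID vectors), `subgraph_edges` (list of
#'   per-cluster [weighted_edge_list()]s), `n_dropped_edges`.
#' @export
partition_graph <- function(gstar, labels) {
  if (!all(gstar$nodes %in% names(labels)))
    stop("labels must cover all nodes of the graph")
  lab <- labels[gstar$nodes]
  canon <- match(lab, sort(unique(lab))) - 1L
  names(canon) <- gstar$nodes
  mu <- length(unique(canon))
  clusters <- split(gstar$nodes, canon)
  idx <- graph_edge_indices(gstar)
  same <- canon[idx[, 1L]] == canon[idx[, 2L]]
  n_dropped <- sum(!same)
  if (n_dropped) gnnsc_log("partition_graph: dropped %d cross-cluster edge(s)", n_dropped)
  sub_edges <- lapply(seq_len(mu) - 1L, function(v) {
    keep <- same & canon[idx[, 1L]] == v
    weighted_edge_list(gstar$nodes[idx[keep, 1L]], gstar$nodes[idx[keep, 2L]],
                       gstar$A[idx[keep, , drop = FALSE]])
  })
  structure(list(labels = canon, mu = mu, clusters = clusters,
                 subgraph_edges = sub_edges, n_dropped_edges = n_dropped),
            class = "cluster_assignment")
}
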