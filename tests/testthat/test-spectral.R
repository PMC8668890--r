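two_cloud_embeddings <- function(n = 20, eps = 0.05, seed = 1) {
  withr::with_seed(seed, {
    half <- n %/% 2
    A <- matrix(rnorm(half * 2, sd = eps), half, 2) +
      matrix(c(1, 0), half, 2, byrow = TRUE)
    B <- matrix(rnorm((n - half) * 2, sd = eps), n - half, 2) +
      matrix(c(-1, 0), n - half, 2, byrow = TRUE)
    emb <- rbind(A, B)
    rownames(emb) <- sprintf("n%02d", seq_len(n))
    list(emb = emb, truth = rep(c(1, 2), c(half, n - half)))
  })
}

test_that("Gaussian kernel matches its closed form", {
  emb <- rbind(a = c(0, 0), b = c(0, 0), c = c(2, 0))
  sim <- gaussian_similarity(emb, omega = sqrt(2))
  expect_equal(sim$W["a", "b"], 1.0)                       # identical points
  expect_equal(sim$W["a", "c"], exp(-1), tolerance = 1e-12) # dist = omega*sqrt(2)
  expect_equal(sim$W, t(sim$W))
  expect_true(all(sim$W > 0 & sim$W <= 1))

  # omega -> infinity: all entries -> 1
  sim_inf <- gaussian_similarity(emb, omega = 1e8)
  expect_true(all(sim_inf$W > 1 - 1e-10))

  # auto bandwidth = median pairwise distance
  set.seed(3)
  emb2 <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  sim_auto <- gaussian_similarity(emb2, omega = "auto")
  d <- as.matrix(dist(emb2))
  expect_equal(sim_auto$omega, median(d[upper.tri(d)][d[upper.tri(d)] > 0]))
  expect_error(gaussian_similarity(emb, omega = -1), "parameter error")
})

test_that("normalized Laplacian matches the 2x2 oracle and its identities", {
  W <- matrix(1, 2, 2)
  L <- normalized_laplacian(W)
  expect_equal(L, matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12)
  expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(0, 1),
               tolerance = 1e-12)

  # D^{1/2} 1 is always an eigenvector with eigenvalue 0
  set.seed(4)
  emb <- matrix(rnorm(24), 12, 2, dimnames = list(sprintf("n%02d", 1:12), NULL))
  sim <- gaussian_similarity(emb, omega = 1)
  L2 <- normalized_laplacian(sim)
  v <- sqrt(rowSums(sim$W))
  expect_equal(max(abs(L2 %*% v)), 0, tolerance = 1e-9)

  # block-diagonal similarity: zero eigenvalue multiplicity = block count
  Wb <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
              cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  ev <- eigen(normalized_laplacian(Wb), symmetric = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 2L)
})

test_that("spectral embedding orders eigenpairs and fixes signs", {
  set.seed(5)
  emb <- matrix(rnorm(30), 15, 2, dimnames = list(sprintf("n%02d", 1:15), NULL))
  sim <- gaussian_similarity(emb, omega = 1)

  se1 <- spectral_embed(sim, mu = 1, row_normalize = FALSE)
  expect_equal(se1$values, 0, tolerance = 1e-9)
  expect_true(all(se1$U >= 0) || all(se1$U <= 0))  # one-signed eigenvector
  expect_gt(se1$U[which.max(abs(se1$U)), 1], 0)    # sign convention

  se_full <- spectral_embed(sim, mu = 15, row_normalize = FALSE)
  expect_equal(se_full$values, sort(se_full$values))
  expect_true(all(se_full$values > -1e-8 & se_full$values < 2 + 1e-8))
  # columns orthonormal before row normalization
  expect_equal(crossprod(se_full$U), diag(15), tolerance = 1e-8)

  expect_error(spectral_embed(sim, mu = 16), "parameter error")
  expect_error(spectral_embed(sim, mu = 0), "parameter error")
})

test_that("two separated clouds are recovered exactly end to end", {
  tc <- two_cloud_embeddings(n = 24, eps = 0.05, seed = 2)
  sim <- gaussian_similarity(tc$emb, omega = "auto")
  se <- spectral_embed(sim, mu = 2)
  labels <- cluster_rows(se, mu = 2, seed = 1)
  expect_equal(ari(labels, tc$truth), 1.0)
  # rows of U are linearly separable by cloud: check group means differ
  mu1 <- colMeans(se$U[tc$truth == 1, , drop = FALSE])
  mu2 <- colMeans(se$U[tc$truth == 2, , drop = FALSE])
  expect_gt(sqrt(sum((mu1 - mu2)^2)), 0.5)
})

test_that("k-means on rows is deterministic and handles degenerate inputs", {
  U <- rbind(matrix(1, 5, 2), matrix(-1, 4, 2))
  rownames(U) <- sprintf("n%d", 1:9)
  se <- structure(list(values = c(0, 0), U = U, row_normalized = FALSE),
                  class = "spectral_embedding")
  lab <- cluster_rows(se, mu = 2, seed = 3)
  expect_equal(length(unique(lab)), 2L)
  expect_true(all(lab[1:5] == lab[1]) && all(lab[6:9] == lab[6]))

  expect_equal(unname(cluster_rows(se, mu = 1, seed = 1)), rep(0L, 9))
  expect_identical(cluster_rows(se, mu = 2, seed = 5),
                   cluster_rows(se, mu = 2, seed = 5))
})

test_that("cluster labels are invariant to node order up to renaming", {
  tc <- two_cloud_embeddings(n = 16, eps = 0.05, seed = 6)
  sim <- gaussian_similarity(tc$emb, omega = "auto")
  se <- spectral_embed(sim, mu = 2)
  lab1 <- cluster_rows(se, mu = 2, seed = 2)
  perm <- withr::with_seed(9, sample.int(nrow(tc$emb)))
  sim_p <- gaussian_similarity(tc$emb[perm, , drop = FALSE], omega = "auto")
  se_p <- spectral_embed(sim_p, mu = 2)
  lab2 <- cluster_rows(se_p, mu = 2, seed = 2)
  expect_equal(ari(lab1[names(lab2)], lab2), 1.0)
})

test_that("graph partition induces subgraphs and drops bridges", {
  # two triangles joined by one bridge
  a <- c("a1", "a1", "a2", "b1", "b1", "b2", "a1")
  b <- c("a2", "a3", "a3", "b2", "b3", "b3", "b1")
  el <- weighted_edge_list(a, b, 1)
  X <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("S1", "S2"), c("a1", "a2", "a3", "b1", "b2", "b3")))
  ds <- expression_dataset(X, c(0L, 1L))
  g <- build_gene_graph(ds, el)
  labels <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_message(ca <- partition_graph(g, labels), "dropped 1")
  expect_equal(ca$mu, 2L)
  expect_equal(ca$n_dropped_edges, 1L)
  expect_setequal(ca$clusters[[1]], c("a1", "a2", "a3"))
  expect_equal(nrow(ca$subgraph_edges[[1]]), 3L)

  # all nodes one label: the single subgraph is the whole graph
  one <- setNames(rep(0L, 6), colnames(X))
  ca1 <- partition_graph(g, one)
  expect_equal(ca1$mu, 1L)
  expect_equal(nrow(ca1$subgraph_edges[[1]]), 7L)

  # non-contiguous labels are canonicalized; isolated singleton allowed
  weird <- setNames(c(5L, 5L, 5L, 9L, 9L, 2L), colnames(X))
  ca2 <- suppressMessages(partition_graph(g, weird))
  expect_setequal(unique(unname(ca2$labels)), 0:2)
})
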