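triangle_graph <- function() {
  states <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  graph_from_parts(states,
                   data.frame(a = c("a", "b", "c"), b = c("b", "c", "a"), w = 1))
}

test_that("negative sampling avoids self, existing edges, and repeats", {
  # triangle: with every edge present, no node has a non-neighbor
  g <- triangle_graph()
  expect_message(s <- build_link_samples(g, gamma = 1, seed = 1), "fewer")
  expect_equal(nrow(s$pos), 3L)
  for (k in seq_len(3)) {
    expect_lte(nrow(s$neg[[k]]), 2L)
    if (nrow(s$neg[[k]])) {
      # no negative may coincide with a graph edge
      adj <- as.matrix(g$A) != 0
      expect_false(any(adj[s$neg[[k]]]))
    }
  }

  # star: the center is adjacent to every leaf, so only leaf-leaf negatives exist
  states <- matrix(rnorm(8), 4, 2,
                   dimnames = list(c("hub", "l1", "l2", "l3"), NULL))
  g2 <- graph_from_parts(states,
                         data.frame(a = "hub", b = c("l1", "l2", "l3"), w = 1))
  s2 <- suppressMessages(build_link_samples(g2, gamma = 1, seed = 2))
  hub_idx <- match("hub", g2$nodes)
  for (k in seq_along(s2$neg)) {
    nm <- s2$neg[[k]]
    if (nrow(nm)) {
      expect_false(any(nm[, 1] == hub_idx & nm[, 2] == hub_idx))
      expect_true(all(nm[, 2] != hub_idx))  # partners are never the hub
      expect_true(all(nm[, 1] != nm[, 2]))
    }
  }

  # determinism
  sA <- suppressMessages(build_link_samples(g2, gamma = 1, seed = 7))
  sB <- suppressMessages(build_link_samples(g2, gamma = 1, seed = 7))
  expect_identical(sA$neg, sB$neg)
})

test_that("gamma negatives are drawn per endpoint when available", {
  study <- generate_synthetic_study(n_samples = 10, n_genes = 40, n_modules = 4,
                                    informative_per_module = 2,
                                    intra_module_edge_prob = 0.5,
                                    inter_module_edge_prob = 0.02, seed = 3)
  g <- build_gene_graph(study$dataset, study$edges)
  s <- build_link_samples(g, gamma = 3, seed = 5)
  sizes <- vapply(s$neg, nrow, 0L)
  expect_true(all(sizes <= 6L))
  expect_true(mean(sizes == 6L) > 0.9)  # sparse graph: full quota almost always
  adj <- as.matrix(g$A) != 0
  neg_all <- do.call(rbind, s$neg)
  expect_false(any(adj[neg_all]))
  expect_true(all(neg_all[, 1] != neg_all[, 2]))
})

test_that("cosine similarity matches hand values and conventions", {
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1.0, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 4)), 1.0, tolerance = 1e-12)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "shape error")
  # symmetry
  withr::with_seed(1, {
    for (i in 1:5) {
      u <- rnorm(4); v <- rnorm(4)
      expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
      expect_lte(abs(cosine_similarity(u, v)), 1 + 1e-12)
    }
  })
})

test_that("link loss matches its closed-form oracles and monotonicity", {
  # two orthogonal unit embeddings: positive pair with sim 0
  H <- rbind(c(1, 0), c(0, 1), c(0, 0))
  s1 <- fake_samples(pos = matrix(c(1L, 2L), 1),
                     neg_list = list(matrix(integer(), 0, 2)),
                     nodes = c("a", "b", "c"))
  expect_equal(link_loss(s1, H), -log(0.5), tolerance = 1e-12)

  # plus one negative with sim 0
  s2 <- fake_samples(pos = matrix(c(1L, 2L), 1),
                     neg_list = list(matrix(c(2L, 3L), 1)),
                     nodes = c("a", "b", "c"))
  H2 <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(link_loss(s2, H2), 2 * -log(0.5), tolerance = 1e-12)

  # loss strictly decreases as positives align and negatives separate
  angle_emb <- function(t) rbind(c(1, 0), c(cos(t), sin(t)), c(-cos(t), -sin(t)))
  losses <- vapply(seq(pi / 2, 0.1, length.out = 8), function(t)
    link_loss(s2, angle_emb(t)), 0)
  expect_true(all(diff(losses) < 0))

  expect_error(link_loss(fake_samples(matrix(integer(), 0, 2), list(), "a"), H),
               "value error")
})

test_that("mean reciprocal rank follows its definition", {
  expect_equal(mean_reciprocal_rank(c(1, 1, 1)), 1.0)
  expect_equal(mean_reciprocal_rank(c(1, 2, 4)), (1 + 0.5 + 0.25) / 3,
               tolerance = 1e-12)
  expect_error(mean_reciprocal_rank(c(1, 0)), "value error")
  expect_error(mean_reciprocal_rank(integer()), "value error")
  # monotone decay for a single worsening rank
  rr <- vapply(c(1, 2, 5, 10, 100), function(n) mean_reciprocal_rank(n), 0)
  expect_true(all(diff(rr) < 0))
})

test_that("a uniform random ranker attains MRR close to H_c / c", {
  c_cand <- 8
  sim <- withr::with_seed(42, {
    mean(1 / sample.int(c_cand, 20000, replace = TRUE))
  })
  expect_equal(sim, random_mrr(c_cand), tolerance = 0.03)
})

test_that("training stops by loss-change rule and is seed-deterministic", {
  study <- generate_synthetic_study(n_samples = 10, n_genes = 30, n_modules = 3,
                                    informative_per_module = 2, seed = 4)
  g <- build_gene_graph(study$dataset, study$edges)
  p0 <- gnn_params(ncol(g$H0), n_layers = 2, hidden_dim = 8, seed = 6)
  s <- build_link_samples(g, gamma = 2, seed = 6)

  # delta = Inf: the first comparable pair of losses triggers the stop
  tr_inf <- train_link_model(g, p0, s, delta = Inf, max_epochs = 50)
  expect_equal(tr_inf$epoch, 2L)
  expect_true(tr_inf$converged)

  tr1 <- suppressWarnings(train_link_model(g, p0, s, delta = 1e-5, max_epochs = 15))
  tr2 <- suppressWarnings(train_link_model(g, p0, s, delta = 1e-5, max_epochs = 15))
  expect_identical(tr1$history, tr2$history)
  expect_true(all(is.finite(tr1$history$loss)))
  expect_equal(tr1$best_mrr, max(tr1$history$mrr))
  expect_warning(train_link_model(g, p0, s, delta = 1e-12, max_epochs = 3),
                 "max_epochs")
})

test_that("gradient descent actually reduces the link loss", {
  study <- generate_synthetic_study(n_samples = 10, n_genes = 40, n_modules = 4,
                                    informative_per_module = 2, seed = 10)
  g <- build_gene_graph(study$dataset, study$edges)
  p0 <- gnn_params(ncol(g$H0), n_layers = 2, hidden_dim = 8, seed = 2)
  s <- build_link_samples(g, gamma = 2, seed = 2)
  tr <- suppressWarnings(train_link_model(g, p0, s, lr = 0.05, delta = 1e-9,
                                          max_epochs = 30))
  expect_lt(tail(tr$history$loss, 1), tr$history$loss[1])
})

test_that("graph augmentation respects threshold, scope, and monotonicity", {
  study <- generate_synthetic_study(n_samples = 10, n_genes = 30, n_modules = 3,
                                    informative_per_module = 2, seed = 5)
  g <- build_gene_graph(study$dataset, study$edges)
  H <- propagate(g, gnn_params(ncol(g$H0), n_layers = 2, hidden_dim = 8, seed = 3))

  # theta = 1: sigma(sim) < 1 always, so G* = G
  g_same <- augment_graph(g, H, theta = 1.0)
  expect_identical(as.matrix(g_same$A), as.matrix(g$A))

  # monotone in theta: higher threshold keeps a subset of edges
  g_lo <- suppressMessages(augment_graph(g, H, theta = 0.55))
  g_hi <- suppressMessages(augment_graph(g, H, theta = 0.65))
  A_lo <- as.matrix(g_lo$A) != 0; A_hi <- as.matrix(g_hi$A) != 0
  expect_true(all(A_hi <= A_lo))
  expect_gte(graph_edge_count(g_lo), graph_edge_count(g))

  # identical embeddings: new edge carries weight sigma(1)
  states <- matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), NULL))
  g3 <- graph_from_parts(states,
                         data.frame(a = c("a", "c"), b = c("c", "b"), w = 1))
  emb <- states
  g3s <- suppressMessages(augment_graph(g3, emb, theta = 0.72))
  expect_equal(g3s$A["a", "b"], 1 / (1 + exp(-1)), tolerance = 1e-12)

  # two-hop scope never scores pairs at distance > 2
  states4 <- matrix(rep(c(1, 0), 4), 4, 2, byrow = TRUE,
                    dimnames = list(c("a", "b", "c", "d"), NULL))
  g4 <- graph_from_parts(states4,
                         data.frame(a = c("a", "b", "c"), b = c("b", "c", "d"),
                                    w = 1))
  g4s <- suppressMessages(augment_graph(g4, states4, theta = 0.6,
                                        candidate_scope = "two_hop"))
  expect_equal(g4s$A["a", "d"], 0)  # identical embeddings, but out of scope
  g4all <- suppressMessages(augment_graph(g4, states4, theta = 0.6,
                                          candidate_scope = "all_pairs"))
  expect_gt(g4all$A["a", "d"], 0)

  expect_error(augment_graph(g, H, theta = 0), "theta")
})
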