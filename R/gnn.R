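#' Create layered aggregation-network parameters
#'
#' One weight matrix per layer, acting on the concatenation of a node's
#' previous state and its neighborhood aggregate; Glorot-uniform initialized
#' from the seed. Layer K maps dimension `2 * d_{K-1}` to `d_K` where `d_0 =
#' input_dim` and `d_K = layer_dims[K]`.
#'
#' @param input_dim dimension of the initial node states (number of samples).
#' @param n_layers number of layers L (default 10).
#' @param hidden_dim output dimension of every layer, or a vector of
#'   per-layer dimensions of length `n_layers`.
#' @param activation one of `"relu"`, `"sigmoid"`, `"tanh"`, `"identity"`.
#' @param seed integer seed for weight initialization.
#' @return A `gnn_params` object: list with `weights` (list of matrices,
#'   `d_K x 2 d_{K-1}`), `activation`, `layer_dims`, `input_dim`, `seed`.
#' @export
gnn_params <- function(input_dim, n_layers = 10, hidden_dim = 32,
                       activation = c("relu", "sigmoid", "tanh", "identity"),
                       seed = 1) {
  activation <- match.arg(activation)
  if (n_layers < 1) stop("n_layers must be >= 1")
  layer_dims <- rep_len(hidden_dim, n_layers)
  dims_in <- c(input_dim, layer_dims[-n_layers])
  weights <- with_seed(seed, lapply(seq_len(n_layers), function(K) {
    fan_in <- 2L * dims_in[K]
    fan_out <- layer_dims[K]
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_out * fan_in, -lim, lim), fan_out, fan_in)
  }))
  structure(list(weights = weights, activation = activation,
                 layer_dims = layer_dims, input_dim = input_dim,
                 seed = as.integer(seed)),
            class = "gnn_params")
}

activation_fun <- function(name) {
  switch(name,
         relu = function(x) pmax(x, 0),
         sigmoid = logistic,
         tanh = tanh,
         identity = identity,
         stop("unknown activation: ", name))
}

# derivative of the activation, as a function of (pre-activation z, value v)
activation_grad <- function(name) {
  switch(name,
         relu = function(z, v) (z > 0) * 1,
         sigmoid = function(z, v) v * (1 - v),
         tanh = function(z, v) 1 - v * v,
         identity = function(z, v) array(1, dim(z)),
         stop("unknown activation: ", name))
}

#' Neighborhood aggregate of one node
#'
#' Weighted mean of the neighbors' current states: each neighbor u of v
#' contributes with coefficient `a_vu = w_vu / sum_u' w_vu'` (edge weights
#' normalized over the neighborhood). Isolated nodes aggregate to the zero
#' vector.
#'
#' @param g a `gene_graph`.
#' @param states numeric matrix of node states, rows named by node.
#' @param node gene ID.
#' @return numeric vector of the same dimension as the states.
#' @export
aggregate_neighborhood <- function(g, states, node) {
  i <- match(node, g$nodes)
  if (is.na(i)) stop("lookup error: node '", node, "' not in graph")
  w <- g$A[i, ]
  nb <- which(w != 0)
  if (!length(nb)) return(numeric(ncol(states)))
  coef <- as.numeric(w[nb]) / sum(w[nb])
  as.numeric(crossprod(states[nb, , drop = FALSE], coef))
}

#' Single node-state update
#'
#' Applies one layer to a node: `v = sigma(W %*% c(prev, agg))`, then L2
#' normalization `v / ||v||`; an all-zero pre-normalization vector is
#' returned unchanged (so isolated all-zero nodes stay zero instead of NaN).
#'
#' @param agg neighborhood aggregate vector.
#' @param prev the node's previous state vector.
#' @param W layer weight matrix, `out_dim x (length(prev) + length(agg))`.
#' @param activation activation name (see [gnn_params()]).
#' @return updated unit-norm (or zero) state vector.
#' @export
update_node_state <- function(agg, prev, W, activation = "relu") {
  cat_in <- c(prev, agg)
  if (ncol(W) != length(cat_in))
    stop("shape error: W expects input dim ", ncol(W), " but got ", length(cat_in))
  v <- activation_fun(activation)(as.numeric(W %*% cat_in))
  nrm <- sqrt(sum(v * v))
  if (nrm > 0) v / nrm else v
}

#' Propagate node states through all layers
#'
#' Runs L synchronous layers of neighborhood aggregation over the whole
#' graph: at layer K every node's aggregate is computed from the layer-(K-1)
#' states, then updated and L2-normalized. Returns the final embeddings
#' H = h^L for all nodes.
#'
#' @param g a `gene_graph`.
#' @param params a [gnn_params()] whose first layer matches `ncol(g$H0)`.
#' @param keep_cache internal: also return per-layer forward quantities for
#'   gradient computation.
#' @return numeric matrix `nodes x layer_dims[L]`, rows named by node, each
#'   nonzero row unit-norm (attribute `layer_index` = L). With
#'   `keep_cache = TRUE`, a list `(H, cache)`.
#' @export
propagate <- function(g, params, keep_cache = FALSE) {
  if (2L * ncol(g$H0) != ncol(params$weights[[1L]]))
    stop("shape error: layer 1 expects input dim ", ncol(params$weights[[1L]]) / 2,
         " but graph states have dim ", ncol(g$H0))
  act <- activation_fun(params$activation)
  Agg_op <- aggregation_operator(g)
  H <- g$H0
  L <- length(params$weights)
  cache <- if (keep_cache) vector("list", L) else NULL
  for (K in seq_len(L)) {
    Agg <- as.matrix(Agg_op %*% H)
    Cat <- cbind(H, Agg)
    Z <- Cat %*% t(params$weights[[K]])
    V <- act(Z)
    Hn <- normalize_rows(V)
    if (any(!is.finite(Hn)))
      stop("numeric error: non-finite state at layer ", K, ", node ",
           g$nodes[which(!is.finite(rowSums(Hn)))[1L]])
    if (keep_cache)
      cache[[K]] <- list(H_prev = H, Agg = Agg, Z = Z, V = V,
                         vnorm = row_norms(V))
    H <- Hn
  }
  rownames(H) <- g$nodes
  attr(H, "layer_index") <- L
  if (keep_cache) list(H = H, cache = cache, Agg_op = Agg_op) else H
}

# Backpropagate dL/dH (gradient at the final embeddings) through the cached
# forward pass; returns the list of per-layer weight gradients.
propagate_backward <- function(params, fwd, dH) {
  L <- length(params$weights)
  agrad <- activation_grad(params$activation)
  Agg_op_t <- Matrix::t(fwd$Agg_op)
  dW <- vector("list", L)
  for (K in rev(seq_len(L))) {
    cc <- fwd$cache[[K]]
    # through row normalization h = v/||v||: dv = (dh - h (dh.h)) / ||v||
    Hn <- cc$V
    nz <- cc$vnorm > 0
    Hn[nz, ] <- Hn[nz, , drop = FALSE] / cc$vnorm[nz]
    dV <- dH - Hn * rowSums(dH * Hn)
    dV[nz, ] <- dV[nz, , drop = FALSE] / cc$vnorm[nz]
    dV[!nz, ] <- 0
    dZ <- dV * agrad(cc$Z, cc$V)
    Cat <- cbind(cc$H_prev, cc$Agg)
    dW[[K]] <- crossprod(dZ, Cat)  # t(dZ) %*% Cat, dims out x 2*in
    dCat <- dZ %*% params$weights[[K]]
    d_in <- ncol(cc$H_prev)
    dH <- dCat[, seq_len(d_in), drop = FALSE] +
      as.matrix(Agg_op_t %*% dCat[, d_in + seq_len(d_in), drop = FALSE])
  }
  dW
}
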