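#' @importFrom stats var sd cor rnorm runif quantile median
#' @importFrom utils read.table write.table head
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# z-score a numeric vector; constant vectors map to all zeros rather than NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Column-wise z-scoring of a matrix (genes in columns).
zscore_cols <- function(X) {
  apply(X, 2, zscore)
}

# L2 norms of matrix rows.
row_norms <- function(M) {
  sqrt(rowSums(M * M))
}

# Normalize rows of M to unit L2 norm; all-zero rows pass through unchanged.
normalize_rows <- function(M) {
  nrm <- row_norms(M)
  nz <- nrm > 0
  M[nz, ] <- M[nz, , drop = FALSE] / nrm[nz]
  M
}

logistic <- function(x) 1 / (1 + exp(-x))

# Canonical unordered-pair key for edge bookkeeping.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

gnnsc_log <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
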