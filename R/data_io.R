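#' Construct an expression dataset
#'
#' The central data container: a samples x genes expression matrix `X` with
#' binary class labels `y`. Genes are always columns internally.
#'
#' @param X numeric matrix, `n_samples x n_genes`.
#' @param y integer vector of class labels in `{0, 1}`, one per sample.
#' @param sample_ids,gene_ids character vectors naming rows / columns of `X`.
#'   Defaults to existing dimnames.
#' @return An object of class `expression_dataset`: a list with elements
#'   `X` (named matrix) and `y` (integer vector named by sample).
#' @export
expression_dataset <- function(X, y, sample_ids = rownames(X), gene_ids = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  if (is.null(gene_ids)) stop("gene_ids are required (gene columns must be named)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) stop("length(sample_ids) must equal nrow(X)")
  if (length(gene_ids) != ncol(X)) stop("length(gene_ids) must equal ncol(X)")
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene IDs: ", paste(utils::head(dup, 10), collapse = ", "))
  }
  if (any(!nzchar(gene_ids))) stop("empty gene IDs are not allowed")
  if (anyNA(X)) stop("X contains missing values; impute or drop before constructing")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y must contain at least one sample of each class")
  dimnames(X) <- list(sample_ids, gene_ids)
  names(y) <- sample_ids
  structure(list(X = X, y = y), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes; classes 0:%d 1:%d\n",
              nrow(x$X), ncol(x$X), sum(x$y == 0L), sum(x$y == 1L)))
  invisible(x)
}

n_samples <- function(ds) nrow(ds$X)
n_genes <- function(ds) ncol(ds$X)

#' Read an expression matrix with labels from delimited text
#'
#' Expects a header row. With `genes_in = "columns"` (the native layout) each
#' row is a sample, each column a gene, plus one label column. With
#' `genes_in = "rows"` the table is transposed on load: rows are genes,
#' columns are samples, and the label row is named `label_column`.
#'
#' @param path path to a TSV/CSV file (delimiter auto-detected from the
#'   header: tab if present, else comma).
#' @param genes_in `"columns"` or `"rows"`.
#' @param label_column name of the label column (or label row when
#'   `genes_in = "rows"`).
#' @param label_map optional named vector mapping raw label values to 0/1,
#'   e.g. `c(tumor = 1, normal = 0)`. Without it, labels must already be 0/1
#'   or have exactly two distinct values, in which case the lexicographically
#'   smaller one maps to 0.
#' @param impute `"none"` (default: missing values are an error) or `"mean"`
#'   for per-gene mean imputation.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, genes_in = c("columns", "rows"),
                                   label_column = "label", label_map = NULL,
                                   impute = c("none", "mean")) {
  genes_in <- match.arg(genes_in)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           row.names = 1)
  if (genes_in == "rows") {
    if (!label_column %in% rownames(tab))
      stop("format error: label row '", label_column, "' not found")
    labels_raw <- unlist(tab[label_column, , drop = TRUE])
    tab <- tab[setdiff(rownames(tab), label_column), , drop = FALSE]
    X <- t(as.matrix(tab))
    mode(X) <- "numeric"
  } else {
    if (!label_column %in% colnames(tab))
      stop("format error: label column '", label_column, "' not found")
    gene_cols <- colnames(tab)[colnames(tab) != label_column]
    if (anyDuplicated(gene_cols)) {
      dup <- unique(gene_cols[duplicated(gene_cols)])
      stop("duplicate gene IDs in header: ",
           paste(utils::head(dup, 10), collapse = ", "))
    }
    labels_raw <- tab[[label_column]]
    X <- as.matrix(tab[, colnames(tab) != label_column, drop = FALSE])
    mode(X) <- "numeric"
  }
  y <- encode_labels(labels_raw, label_map)
  if (anyNA(X)) {
    n_miss <- sum(is.na(X))
    if (impute == "mean") {
      X <- apply(X, 2, function(col) {
        col[is.na(col)] <- mean(col, na.rm = TRUE)
        col
      })
      gnnsc_log("imputed %d missing values with per-gene means", n_miss)
    } else {
      stop(n_miss, " missing expression values; rerun with impute = \"mean\" or clean the file")
    }
  }
  expression_dataset(X, y)
}

detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

encode_labels <- function(labels_raw, label_map = NULL) {
  if (!is.null(label_map)) {
    miss <- setdiff(unique(as.character(labels_raw)), names(label_map))
    if (length(miss))
      stop("label error: values not covered by label_map: ", paste(miss, collapse = ", "))
    return(as.integer(label_map[as.character(labels_raw)]))
  }
  u <- sort(unique(as.character(labels_raw)))
  if (all(u %in% c("0", "1"))) return(as.integer(as.character(labels_raw)))
  if (length(u) != 2L)
    stop("label error: expected binary labels, got {", paste(u, collapse = ", "), "}")
  as.integer(as.character(labels_raw) == u[2L])
}

#' Write an expression dataset to TSV
#'
#' Inverse of [read_expression_matrix()] for the genes-in-columns layout.
#'
#' @param ds an [expression_dataset()].
#' @param path output path.
#' @param label_column name for the label column.
#' @export
write_expression_matrix <- function(ds, path, label_column = "label") {
  tab <- data.frame(sample_id = rownames(ds$X), ds$X, check.names = FALSE)
  tab[[label_column]] <- ds$y
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a weighted edge list
#'
#' Undirected gene-gene interactions with positive weights, such as the
#' physical-interaction relation exported from an interaction resource
#' (GeneMANIA-style). Self-loops are dropped with a warning; duplicate
#' unordered pairs are collapsed keeping the maximum weight.
#'
#' @param gene_a,gene_b character vectors of endpoint gene IDs.
#' @param weight positive numeric weights (recycled).
#' @return A `weighted_edge_list`: a data.frame with columns `gene_a`,
#'   `gene_b`, `weight`, one row per unordered pair.
#' @export
weighted_edge_list <- function(gene_a, gene_b, weight = 1) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  weight <- as.numeric(rep_len(weight, length(gene_a)))
  if (length(gene_b) != length(gene_a)) stop("gene_a and gene_b lengths differ")
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("edge weights must be positive and finite")
  loops <- gene_a == gene_b
  if (any(loops)) {
    gnnsc_log("dropped %d self-loop edge record(s)", sum(loops))
    gene_a <- gene_a[!loops]; gene_b <- gene_b[!loops]; weight <- weight[!loops]
  }
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  df <- data.frame(gene_a = a, gene_b = b, weight = weight,
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    # max weight per unordered pair, then canonical ordering for determinism
    key <- pair_key(df$gene_a, df$gene_b)
    w <- tapply(df$weight, key, max)
    df <- df[!duplicated(key), , drop = FALSE]
    df$weight <- as.numeric(w[pair_key(df$gene_a, df$gene_b)])
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("weighted_edge_list", "data.frame")
  df
}

#' Read a weighted edge list from delimited text
#'
#' Accepts 2-column (`gene_a gene_b`) or 3-column (`gene_a gene_b weight`)
#' whitespace/tab-delimited text; lines starting with `#` are comments.
#'
#' @param path input path.
#' @param default_weight weight assigned to 2-column records.
#' @return A [weighted_edge_list()].
#' @export
read_edge_list <- function(path, default_weight = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (default_weight <= 0) stop("default_weight must be positive")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(weighted_edge_list(character(), character()))
  parts <- strsplit(trimws(lines), "[\t ]+")
  # tolerate a header row: named columns, or a non-numeric weight field
  first <- parts[[1L]]
  is_header <- identical(tolower(first[1:2]), c("gene_a", "gene_b")) ||
    (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[[3L]]))))
  if (is_header) parts <- parts[-1L]
  if (!length(parts)) return(weighted_edge_list(character(), character()))
  ncols <- lengths(parts)
  if (any(ncols < 2L | ncols > 3L))
    stop("edge list rows must have 2 or 3 fields; offending line(s): ",
         paste(which(ncols < 2L | ncols > 3L), collapse = ", "))
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  w <- vapply(parts, function(p) {
    if (length(p) >= 3L) as.numeric(p[[3L]]) else as.numeric(default_weight)
  }, 0)
  if (anyNA(w)) stop("non-numeric edge weight in edge list")
  weighted_edge_list(a, b, w)
}

#' Write a weighted edge list to TSV
#' @param edges a [weighted_edge_list()].
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rename probe IDs to gene symbols
#'
#' Applies a two-column probe-to-gene mapping (as pre-exported from an
#' annotation service) to the dataset's columns. Probes absent from the map
#' are dropped; when several probes map to the same gene, the probe with the
#' highest variance across samples is kept.
#'
#' @param ds an [expression_dataset()] whose gene IDs are probe IDs.
#' @param map data.frame with columns `probe_id` and `gene_symbol` (or any
#'   two columns in that order), or a path to a 2-column TSV.
#' @return An [expression_dataset()] with gene symbols as gene IDs.
#' @export
apply_probe_map <- function(ds, map) {
  if (is.character(map) && length(map) == 1L) {
    map <- utils::read.table(map, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
  }
  if (ncol(map) < 2L) stop("probe map must have two columns")
  probes <- as.character(map[[1L]])
  symbols <- as.character(map[[2L]])
  keep <- probes %in% colnames(ds$X)
  if (!any(keep)) stop("mapping error: no overlap between dataset probes and map")
  probes <- probes[keep]; symbols <- symbols[keep]
  n_dropped <- ncol(ds$X) - length(unique(probes))
  if (n_dropped > 0) gnnsc_log("dropped %d unmapped probe column(s)", n_dropped)
  vars <- apply(ds$X[, probes, drop = FALSE], 2, stats::var)
  # per gene symbol keep the highest-variance probe (ties: first in map order)
  ord <- order(symbols, -vars)
  first <- !duplicated(symbols[ord])
  chosen <- probes[ord][first]
  chosen_sym <- symbols[ord][first]
  X <- ds$X[, chosen, drop = FALSE]
  colnames(X) <- chosen_sym
  expression_dataset(X, ds$y, sample_ids = rownames(ds$X))
}

#' Summarize an expression dataset
#'
#' Reports sample/gene counts, per-class counts, and the unbalance rate
#' UR = majority count / minority count rounded to two decimals. Note:
#' max/min counts give 58/19 = 3.05 for a 58-vs-19 study; for a 52-vs-50
#' study the same definition gives 1.04 (some published tables print other
#' values for near-balanced designs under unstated definitions).
#'
#' @param ds an [expression_dataset()].
#' @return list with `n_samples`, `n_genes`, `class_counts` (named 0/1),
#'   `unbalance_rate`.
#' @export
summarize_dataset <- function(ds) {
  counts <- c("0" = sum(ds$y == 0L), "1" = sum(ds$y == 1L))
  list(
    n_samples = n_samples(ds),
    n_genes = n_genes(ds),
    class_counts = counts,
    unbalance_rate = round(max(counts) / min(counts), 2)
  )
}

#' Write a feature ranking to TSV
#'
#' Columns: rank, gene_id, cluster_id, score, selected (1 for the per-cluster
#' biomarker).
#'
#' @param ranking a `feature_ranking` from [select_biomarkers()].
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  ent <- ranking$entries
  out <- data.frame(rank = seq_len(nrow(ent)),
                    gene_id = ent$gene_id,
                    cluster_id = ent$cluster_id,
                    score = sprintf("%.10g", ent$score),
                    selected = as.integer(ent$gene_id %in% ranking$selected))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
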