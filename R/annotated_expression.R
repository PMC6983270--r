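#' Construct an annotated expression object
#'
#' The central container of the package: a genes x cells matrix of
#' log-normalized expression together with a cell -> cluster assignment and an
#' optional gene -> gene-cluster assignment (the clustered-marker-file triplet
#' produced by ICGS-style workflows, held in one structure).
#'
#' @param values Numeric genes x cells matrix with unique, non-empty row
#'   (gene) and column (cell) names. Values must be finite and non-negative.
#' @param cell_cluster Vector of cluster labels, one per cell. Either named by
#'   cell or in column order of `values`. Labels may be character or numeric;
#'   [standardize_labels()] converts them to 1..K integers.
#' @param gene_cluster Optional vector of gene-cluster labels, one per gene
#'   (named by gene or in row order).
#' @return An object of class `annotated_expression`: a list with elements
#'   `values`, `cell_cluster` (named, per cell) and `gene_cluster` (named, per
#'   gene, or `NULL`).
#' @export
annotated_expression <- function(values, cell_cluster, gene_cluster = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and cell column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate cell identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")

  cell_cluster <- align_labels(cell_cluster, colnames(values), "cell")
  if (!is.null(gene_cluster)) {
    gene_cluster <- align_labels(gene_cluster, rownames(values), "gene")
  }
  structure(
    list(values = values, cell_cluster = cell_cluster, gene_cluster = gene_cluster),
    class = "annotated_expression"
  )
}

# match a label vector to an identifier axis, by name when named
align_labels <- function(labels, ids, what) {
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing)) {
      stop("no ", what, "-cluster label for: ", paste(missing, collapse = ", "))
    }
    labels <- labels[ids]
  } else {
    if (length(labels) != length(ids)) {
      stop(what, "-cluster labels must have one entry per ", what)
    }
    names(labels) <- ids
  }
  if (anyNA(labels)) stop("missing ", what, "-cluster labels")
  labels
}

#' @exportS3Method base::print
print.annotated_expression <- function(x, ...) {
  k <- length(unique(x$cell_cluster))
  cat(sprintf("annotated_expression: %d genes x %d cells, %d cell cluster%s%s\n",
              nrow(x$values), ncol(x$values), k, if (k == 1) "" else "s",
              if (is.null(x$gene_cluster)) "" else
                sprintf(", %d gene clusters", length(unique(x$gene_cluster)))))
  invisible(x)
}

#' @export
dim.annotated_expression <- function(x) dim(x$values)

#' Subset an annotated expression object by genes and/or cells
#'
#' @param x An `annotated_expression`.
#' @param genes,cells Character vectors (or logical/integer indices) selecting
#'   rows and columns; `NULL` keeps the axis unchanged.
#' @return An `annotated_expression` restricted to the selection.
#' @export
subset_expression <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "annotated_expression"))
  if (is.null(genes)) genes <- rownames(x$values)
  if (is.null(cells)) cells <- colnames(x$values)
  v <- x$values[genes, cells, drop = FALSE]
  annotated_expression(
    v,
    cell_cluster = x$cell_cluster[colnames(v)],
    gene_cluster = if (is.null(x$gene_cluster)) NULL else x$gene_cluster[rownames(v)]
  )
}

# cells of each cluster, in current column order, as a named list whose
# elements follow the clusters' order of first appearance along the cell axis
cluster_cells <- function(x) {
  lab <- x$cell_cluster[colnames(x$values)]
  split(colnames(x$values), factor(lab, levels = unique(lab)))
}
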