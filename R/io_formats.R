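#' Read clustered expression input files
#'
#' Reads the pair of tab-delimited files produced by ICGS-style unsupervised
#' workflows: a clustered marker-gene expression file and a groups file, plus
#' an optional full expression matrix. The expression dialect is: row 1 holds
#' cell identifiers, row 2 is `column_clusters-flat` with the per-cell numeric
#' cluster, column 1 holds gene identifiers and an optional column 2
#' `row_clusters-flat` carries per-gene gene-cluster ids; the remaining body is
#' numeric. The groups file has two tab-separated columns (cell id, cluster
#' label) and no header. Cell-cluster labels are taken from the groups file;
#' gene clusters from the expression file when present.
#'
#' Upstream quality control is assumed done: the reader validates identifiers
#' and values but never filters cells.
#'
#' @param expression_path Path to the clustered marker expression file.
#' @param groups_path Path to the groups file.
#' @param full_expression_path Optional path to a full genes x cells
#'   tab-delimited matrix (first column gene ids, header cell ids), or a
#'   length-3 character vector `c(mtx, barcodes, features)` naming a
#'   MatrixMarket triplet which is densified on load.
#' @return A list with `marker` (an [annotated_expression()]) and `full`
#'   (an `annotated_expression` over all genes, or `NULL`).
#' @export
read_icgs <- function(expression_path, groups_path, full_expression_path = NULL) {
  for (p in c(expression_path, groups_path, full_expression_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  raw <- utils::read.delim(expression_path, header = FALSE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) < 3L || ncol(raw) < 2L) stop("malformed expression file: ", expression_path)

  has_gene_clusters <- identical(raw[1L, 2L], "row_clusters-flat")
  first_data_col <- if (has_gene_clusters) 3L else 2L
  if (!identical(raw[2L, 1L], "column_clusters-flat")) {
    stop("malformed expression file (row 2 must be 'column_clusters-flat'): ",
         expression_path)
  }
  cells <- as.character(raw[1L, first_data_col:ncol(raw)])
  genes <- as.character(raw[3:nrow(raw), 1L])
  if (anyDuplicated(cells)) {
    stop("duplicate cell identifiers in ", expression_path, ": ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "))
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers in ", expression_path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }

  body <- as.matrix(raw[3:nrow(raw), first_data_col:ncol(raw), drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = length(genes),
                                    dimnames = list(genes, cells)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', cell '%s' in %s",
                 genes[bad[1L]], cells[bad[2L]], expression_path))
  }

  groups <- utils::read.delim(groups_path, header = FALSE, sep = "\t",
                              colClasses = "character")
  if (ncol(groups) < 2L) stop("groups file must have two tab-separated columns")
  grp_cells <- groups[[1L]]
  if (anyDuplicated(grp_cells)) {
    stop("duplicate cell identifiers in groups file: ",
         paste(unique(grp_cells[duplicated(grp_cells)]), collapse = ", "))
  }
  only_groups <- setdiff(grp_cells, cells)
  only_expr <- setdiff(cells, grp_cells)
  if (length(only_groups) || length(only_expr)) {
    stop("cell sets of groups and expression files differ",
         if (length(only_groups)) paste0("; only in groups: ",
                                         paste(only_groups, collapse = ", ")) else "",
         if (length(only_expr)) paste0("; only in expression: ",
                                       paste(only_expr, collapse = ", ")) else "")
  }
  cell_cluster <- stats::setNames(groups[[2L]], grp_cells)[cells]

  gene_cluster <- NULL
  if (has_gene_clusters) {
    gene_cluster <- stats::setNames(as.character(raw[3:nrow(raw), 2L]), genes)
  }
  marker <- annotated_expression(values, cell_cluster, gene_cluster)

  full <- NULL
  if (!is.null(full_expression_path)) {
    fv <- read_full_matrix(full_expression_path)
    missing <- setdiff(cells, colnames(fv))
    if (length(missing)) {
      stop("full matrix is missing cells present in the marker file: ",
           paste(missing, collapse = ", "))
    }
    full <- annotated_expression(fv[, cells, drop = FALSE], cell_cluster)
  }
  list(marker = marker, full = full)
}

# full matrix as dense numeric: plain TSV or an MTX triplet
read_full_matrix <- function(path) {
  if (length(path) == 3L) {
    m <- as.matrix(Matrix::readMM(path[[1L]]))
    barcodes <- utils::read.delim(path[[2L]], header = FALSE)[[1L]]
    features <- utils::read.delim(path[[3L]], header = FALSE)[[1L]]
    dimnames(m) <- list(as.character(features), as.character(barcodes))
    return(m)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write an annotated expression object in the clustered-expression dialect
#'
#' Inverse of the expression half of [read_icgs()]; values are written with
#' full (17 significant digit) precision so a write/read round trip reproduces
#' them bit-identically.
#'
#' @param x An [annotated_expression()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_icgs <- function(x, path) {
  stopifnot(inherits(x, "annotated_expression"))
  v <- x$values
  has_gc <- !is.null(x$gene_cluster)
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c("UID", if (has_gc) "row_clusters-flat", colnames(v))
  writeLines(paste(header, collapse = "\t"), con)
  cl_row <- c("column_clusters-flat", if (has_gc) "",
              as.character(x$cell_cluster[colnames(v)]))
  writeLines(paste(cl_row, collapse = "\t"), con)
  num <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  rows <- cbind(rownames(v),
                if (has_gc) as.character(x$gene_cluster[rownames(v)]),
                num)
  writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a groups file (cell id, cluster label; no header)
#'
#' @param x An [annotated_expression()] or a two-column data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(x, path) {
  df <- if (inherits(x, "annotated_expression")) {
    data.frame(cell = colnames(x$values),
               cluster = as.character(x$cell_cluster[colnames(x$values)]))
  } else as.data.frame(x)[, 1:2]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble the tabular result bundle of a run
#'
#' @param drs_doublet_table Per-cell data frame: cell, original cluster, best
#'   match label, similarity, putative-doublet flag.
#' @param drs_results Cells x references DCP matrix.
#' @param final_doublets_groups,final_nondoublets_groups Data frames with
#'   columns cell, label, state; the two cell sets must partition the input.
#' @param final_doublets_exp,final_nondoublets_exp Expression subsets
#'   (genes x cells matrices) for the two cell sets.
#' @param synthetic_dcps Synthetic profiles x references DCP matrix.
#' @return An object of class `output_bundle`.
#' @export
output_bundle <- function(drs_doublet_table, drs_results,
                          final_doublets_groups, final_nondoublets_groups,
                          final_doublets_exp, final_nondoublets_exp,
                          synthetic_dcps) {
  doub <- final_doublets_groups$cell
  nondoub <- final_nondoublets_groups$cell
  all_cells <- drs_doublet_table$cell
  if (length(intersect(doub, nondoub)) ||
      !setequal(c(doub, nondoub), all_cells)) {
    stop("doublet and non-doublet cell sets must partition the input cells")
  }
  if (!all(all_cells %in% rownames(drs_results))) {
    stop("every cell must have a DCP row in drs_results")
  }
  structure(list(
    drs_doublet_table = drs_doublet_table,
    drs_results = drs_results,
    final_doublets_groups = final_doublets_groups,
    final_nondoublets_groups = final_nondoublets_groups,
    final_doublets_exp = final_doublets_exp,
    final_nondoublets_exp = final_nondoublets_exp,
    synthetic_dcps = synthetic_dcps
  ), class = "output_bundle")
}

#' Write the seven tabular output files of a run
#'
#' Emits `DRS_doublet_table.txt`, `DRS_results.txt`,
#' `Final_doublets_groups.txt`, `Final_nondoublets_groups.txt`,
#' `Final_doublets_exp.txt`, `Final_nondoublets_exp.txt` and
#' `Synthetic_doublet_DCPs.txt` into `directory`, with deterministic row order
#' (input cell order).
#'
#' @param bundle An [output_bundle()].
#' @param directory Output directory (created if absent).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_outputs <- function(bundle, directory) {
  stopifnot(inherits(bundle, "output_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", directory)
  }
  wt <- function(df, name, rn = FALSE) {
    p <- file.path(directory, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
    p
  }
  wexp <- function(m, name) {
    p <- file.path(directory, name)
    df <- cbind(UID = rownames(m), as.data.frame(matrix(sprintf("%.17g", m),
                nrow = nrow(m), dimnames = dimnames(m)), check.names = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    p
  }
  paths <- c(
    wt(bundle$drs_doublet_table, "DRS_doublet_table.txt"),
    wt(as.data.frame(bundle$drs_results), "DRS_results.txt", rn = TRUE),
    wt(bundle$final_doublets_groups, "Final_doublets_groups.txt"),
    wt(bundle$final_nondoublets_groups, "Final_nondoublets_groups.txt"),
    wexp(bundle$final_doublets_exp, "Final_doublets_exp.txt"),
    wexp(bundle$final_nondoublets_exp, "Final_nondoublets_exp.txt"),
    wt(as.data.frame(bundle$synthetic_dcps), "Synthetic_doublet_DCPs.txt", rn = TRUE)
  )
  invisible(paths)
}

#' Convert Seurat-style exports to the clustered-expression inputs
#'
#' Takes a normalized expression matrix, a marker table (gene, cluster, rank)
#' and per-cell cluster identities — the three objects a Seurat analysis
#' exports — and builds the marker expression object, groups table and full
#' expression object this package consumes. The marker object contains exactly
#' the union of each cluster's `top_n` best-ranked markers (deduplicated),
#' with cells grouped by cluster (stable within-cluster input order) and
#' markers carrying their source cluster as the gene cluster.
#'
#' @param normalized_expression Genes x cells numeric matrix (or data frame)
#'   of normalized expression, or a path to a TSV/CSV with gene ids in the
#'   first column.
#' @param marker_table Data frame with columns `gene`, `cluster` and `rank`
#'   (smaller rank = stronger marker), or a path to such a TSV.
#' @param cluster_identities Data frame with columns `cell` and `cluster` (or
#'   a named vector cell -> cluster), or a path to such a TSV.
#' @param top_n Markers retained per cluster (50 is the conventional choice).
#' @param is_log Set to `FALSE` when `normalized_expression` is on the linear
#'   scale; values are then converted to `log2(x + 1)`.
#' @return List with `marker` ([annotated_expression()]), `groups` (data
#'   frame cell, cluster) and `full` (`annotated_expression` over all genes).
#' @export
seurat_prep <- function(normalized_expression, marker_table, cluster_identities,
                        top_n = 50, is_log = TRUE) {
  if (is.character(normalized_expression) && length(normalized_expression) == 1L) {
    sep <- if (grepl("\\.csv$", normalized_expression)) "," else "\t"
    normalized_expression <- as.matrix(utils::read.delim(
      normalized_expression, sep = sep, row.names = 1L, check.names = FALSE))
  }
  expr <- as.matrix(normalized_expression)
  if (is.character(marker_table) && length(marker_table) == 1L) {
    marker_table <- utils::read.delim(marker_table, sep = "\t",
                                      colClasses = c("character", "character", "numeric"))
  }
  marker_table <- as.data.frame(marker_table)
  names(marker_table)[1:3] <- c("gene", "cluster", "rank")
  if (is.character(cluster_identities) && length(cluster_identities) == 1L) {
    cluster_identities <- utils::read.delim(cluster_identities, sep = "\t",
                                            colClasses = "character")
  }
  if (is.null(dim(cluster_identities))) {
    idents <- data.frame(cell = names(cluster_identities),
                         cluster = as.character(cluster_identities))
  } else {
    idents <- as.data.frame(cluster_identities)[, 1:2]
    names(idents) <- c("cell", "cluster")
    idents$cluster <- as.character(idents$cluster)
  }
  missing_cells <- setdiff(idents$cell, colnames(expr))
  if (length(missing_cells)) {
    stop("identity cells absent from the expression matrix: ",
         paste(missing_cells, collapse = ", "))
  }
  empty <- setdiff(unique(marker_table$cluster), unique(idents$cluster))
  if (length(empty)) stop("empty cluster (markers but no cells): ",
                          paste(empty, collapse = ", "))

  if (!is_log) expr <- log2(expr + 1)

  absent <- setdiff(unique(marker_table$gene), rownames(expr))
  if (length(absent)) {
    warning("dropping marker genes absent from the expression matrix: ",
            paste(absent, collapse = ", "))
    marker_table <- marker_table[!marker_table$gene %in% absent, , drop = FALSE]
  }

  # top_n best-ranked markers per cluster, clusters in sorted-label order
  cl_order <- order_labels(unique(idents$cluster))
  marker_genes <- character(0)
  marker_gc <- character(0)
  for (cl in cl_order) {
    mt <- marker_table[marker_table$cluster == cl, , drop = FALSE]
    mt <- mt[order(mt$rank), , drop = FALSE]
    sel <- utils::head(mt$gene, top_n)
    new <- setdiff(sel, marker_genes)
    marker_genes <- c(marker_genes, new)
    marker_gc <- c(marker_gc, rep(cl, length(new)))
  }
  if (!length(marker_genes)) stop("no marker genes left after filtering")

  ord <- order(match(idents$cluster, cl_order))  # stable: keeps input order within cluster
  cells <- idents$cell[ord]
  cell_cluster <- stats::setNames(idents$cluster[ord], cells)

  marker <- annotated_expression(
    expr[marker_genes, cells, drop = FALSE],
    cell_cluster,
    gene_cluster = stats::setNames(marker_gc, marker_genes)
  )
  full <- annotated_expression(expr[, cells, drop = FALSE], cell_cluster)
  list(marker = marker,
       groups = data.frame(cell = cells, cluster = unname(cell_cluster)),
       full = full)
}

# sort labels numerically when all parse as numbers, lexicographically otherwise
order_labels <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) labels[order(num)] else sort(labels)
}
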