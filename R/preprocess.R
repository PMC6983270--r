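#' Standardize cluster labels to ascending integers
#'
#' Converts cell-cluster and gene-cluster labels to `1..K` integers in order
#' of first appearance along the (cluster-contiguous) cell or gene axis, which
#' preserves the left-to-right ordering of the clustered heatmap the input
#' came from. Expression values are untouched; the returned maps record the
#' original label for each numeric id.
#'
#' @param x An [annotated_expression()].
#' @return List with `expression` (relabelled `annotated_expression`),
#'   `cell_map` and `gene_map` (named character vectors, numeric id ->
#'   original label; `gene_map` is `NULL` without gene clusters).
#' @export
standardize_labels <- function(x) {
  stopifnot(inherits(x, "annotated_expression"))
  std <- function(labels) {
    lev <- unique(as.character(labels))
    new <- stats::setNames(match(as.character(labels), lev), names(labels))
    list(labels = new, map = stats::setNames(lev, seq_along(lev)))
  }
  cc <- std(x$cell_cluster[colnames(x$values)])
  gc <- if (is.null(x$gene_cluster)) NULL else std(x$gene_cluster[rownames(x$values)])
  out <- annotated_expression(x$values, cc$labels,
                              if (is.null(gc)) NULL else gc$labels)
  list(expression = out, cell_map = cc$map,
       gene_map = if (is.null(gc)) NULL else gc$map)
}

#' Read a GMT gene set file
#'
#' @param path Path to a GMT file (tab-separated: set name, description, then
#'   gene symbols).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    stats::setNames(list(unique(f[-(1:2)])), f[1L])
  })
  unlist(sets, recursive = FALSE)
}

#' Bundled cell-cycle gene sets
#'
#' Returns the static KEGG-cell-cycle-derived symbol list shipped with the
#' package for the requested species. Users needing a different or updated
#' set can pass their own GMT file to [remove_cell_cycle()].
#'
#' @param species `"Hs"` (human, upper-case symbols) or `"Mm"` (mouse,
#'   title-case symbols).
#' @return Named list with one character vector of gene symbols.
#' @export
cell_cycle_sets <- function(species = c("Hs", "Mm")) {
  species <- match.arg(species)
  gmt <- system.file("extdata", "kegg_cell_cycle.gmt", package = "decondoublet",
                     mustWork = TRUE)
  sets <- read_gmt(gmt)
  sets[grepl(paste0("_", toupper(species), "$"), names(sets))]
}

#' Remove cell-cycle-associated gene clusters
#'
#' Screens every gene cluster for enrichment of cell-cycle genes with a
#' one-sided hypergeometric test against the universe of all genes in the
#' expression object, adjusts the per-cluster p-values with
#' Benjamini-Hochberg, and removes every gene of each significantly enriched
#' cluster (adjusted p <= `alpha`) from all downstream analyses.
#'
#' @param x An [annotated_expression()] with gene clusters.
#' @param gene_sets Named list of gene symbol vectors (e.g.
#'   [cell_cycle_sets()] or [read_gmt()] output). Multiple sets are pooled.
#' @param alpha Adjusted-p cutoff in (0, 1]; 0.05 by convention. `alpha = 0`
#'   removes nothing.
#' @return List with `expression` (genes of significant clusters removed),
#'   `removed_genes`, and `report` (data frame: gene cluster, cluster size,
#'   overlap with the pooled set, raw and BH-adjusted p, removed flag).
#' @export
remove_cell_cycle <- function(x, gene_sets = cell_cycle_sets("Hs"), alpha = 0.05) {
  stopifnot(inherits(x, "annotated_expression"))
  if (is.null(x$gene_cluster)) {
    stop("no gene clusters present; run without cell-cycle removal ",
         "(removeCC = FALSE) or supply gene-clustered input")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop("alpha must be a single value in [0, 1)")
  }
  universe <- rownames(x$values)
  cc_genes <- intersect(unique(unlist(gene_sets, use.names = FALSE)), universe)
  gc <- x$gene_cluster[universe]
  clusters <- unique(gc)

  report <- do.call(rbind, lapply(clusters, function(cl) {
    members <- universe[gc == cl]
    k <- length(members)
    q <- length(intersect(members, cc_genes))
    # P(X >= q) drawing k from a universe with |cc| successes
    p <- stats::phyper(q - 1L, length(cc_genes),
                       length(universe) - length(cc_genes), k,
                       lower.tail = FALSE)
    data.frame(gene_cluster = cl, size = k, overlap = q, p = p,
               stringsAsFactors = FALSE)
  }))
  report$p_adj <- stats::p.adjust(report$p, method = "BH")
  report$removed <- report$p_adj <= alpha & alpha > 0
  removed_clusters <- report$gene_cluster[report$removed]
  removed_genes <- universe[gc %in% removed_clusters]

  out <- if (length(removed_genes)) {
    subset_expression(x, genes = setdiff(universe, removed_genes))
  } else x
  list(expression = out, removed_genes = removed_genes, report = report)
}
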