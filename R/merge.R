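#' Per-cluster reference signatures
#'
#' Computes one signature column per cell cluster over the supplied marker
#' genes: the centroid (per-gene arithmetic mean over the cluster's cells,
#' default) or the marginal medoid (per-gene median), the latter being the
#' robust choice when doublets contribute visibly to cluster averages.
#'
#' @param x An [annotated_expression()].
#' @param mode `"centroid"` or `"medoid"`.
#' @return Genes x K numeric matrix, columns named by cluster id in order of
#'   first appearance along the cell axis.
#' @export
compute_signatures <- function(x, mode = c("centroid", "medoid")) {
  stopifnot(inherits(x, "annotated_expression"))
  mode <- match.arg(mode)
  cl <- cluster_cells(x)
  if (any(lengths(cl) == 0L)) {
    stop("empty cluster: ", paste(names(cl)[lengths(cl) == 0L], collapse = ", "))
  }
  sig <- vapply(cl, function(cells) {
    m <- x$values[, cells, drop = FALSE]
    if (mode == "centroid") rowMeans(m) else apply(m, 1L, stats::median)
  }, numeric(nrow(x$values)))
  sig <- matrix(sig, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), names(cl)))
  sig
}

#' Markov clustering of a symmetric binary graph
#'
#' Partitions the nodes of an undirected graph given as a symmetric binary
#' adjacency matrix by iterating expansion (matrix power of the
#' column-stochastic flow matrix) and inflation (elementwise power followed by
#' column renormalization) to convergence, then reading clusters off the
#' attractor rows. Nodes attracted by more than one attractor are assigned to
#' the lowest-indexed cluster.
#'
#' @param B Symmetric binary (0/1) adjacency matrix.
#' @param expansion Matrix power applied at each iteration (integer >= 2).
#' @param inflation Elementwise power applied at each iteration (> 1).
#' @param add_loops Add self-loops before normalization (recommended; removes
#'   dependence on path parity).
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the max-norm difference of successive
#'   flow matrices.
#' @return Integer vector of cluster ids (1-based, in order of cluster
#'   discovery), one per node.
#' @export
mcl <- function(B, expansion = 2, inflation = 2, add_loops = TRUE,
                max_iter = 100L, tol = 1e-6) {
  B <- as.matrix(B)
  if (!isSymmetric(unname(B)) || !all(B %in% c(0, 1))) {
    stop("B must be a symmetric binary matrix")
  }
  n <- nrow(B)
  M <- B
  if (add_loops) diag(M) <- 1
  normalize <- function(m) sweep(m, 2L, pmax(colSums(m), .Machine$double.xmin), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Mnew <- normalize(Mexp ^ inflation)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("Markov clustering did not converge in %d iterations (residual %.3g)",
                 max_iter, delta))
  }
  # attractors: rows with mass on the diagonal; their supported columns form clusters
  thr <- tol * 10
  attractors <- which(diag(M) > thr)
  assignment <- integer(n)
  next_id <- 0L
  for (a in attractors) {
    members <- which(M[a, ] > thr)
    unassigned <- members[assignment[members] == 0L]
    if (!length(unassigned)) next
    if (assignment[a] != 0L) {
      assignment[unassigned] <- assignment[a]
    } else {
      next_id <- next_id + 1L
      assignment[c(a, unassigned)] <- next_id
    }
  }
  for (i in which(assignment == 0L)) {  # isolated numerical stragglers
    next_id <- next_id + 1L
    assignment[i] <- next_id
  }
  assignment
}

#' Merge transcriptionally similar clusters
#'
#' Computes the Pearson correlation matrix `r` of the cluster signatures, the
#' merge threshold `rho_T = mean(r_ij) + rho_prime * sd(r_ij)` over the
#' off-diagonal upper triangle, binarizes `r` at `rho_T`, and — when at least
#' one pair passes — partitions the binary graph with Markov clustering.
#' Merged signatures are recomputed from the pooled member cells of each
#' merged cluster, so downstream deconvolution sees true merged references.
#'
#' With exactly two clusters the dispersion of a single correlation is
#' undefined and the threshold degenerates to `r_12` itself, which would force
#' a merge at any `rho_prime`; two-cluster inputs are therefore never merged
#' unless their signatures are identical (`r_12 = 1`).
#'
#' @param x An [annotated_expression()] (standardized labels recommended).
#' @param rho_prime Threshold scaling; lower values merge more clusters.
#'   Typical range 0.5-1.5, conventional default 1.
#' @param mode Passed to [compute_signatures()].
#' @param mcl_params Named list of overrides for [mcl()] arguments.
#' @return List of class `merge_decision`: `r` (K x K correlation matrix),
#'   `rho_prime`, `rho_T`, `B` (binary matrix, diagonal forced 1),
#'   `partition` (named map original cluster -> merged cluster id),
#'   `signatures` (genes x n merged reference matrix), `mode`, and
#'   `provenance` (merged id -> original clusters).
#' @export
merge_clusters <- function(x, rho_prime = 1, mode = c("centroid", "medoid"),
                           mcl_params = list()) {
  stopifnot(inherits(x, "annotated_expression"))
  mode <- match.arg(mode)
  if (!is.numeric(rho_prime) || !is.finite(rho_prime)) {
    stop("rho_prime must be finite")
  }
  sig <- compute_signatures(x, mode)
  K <- ncol(sig)
  if (K < 2L) stop("cluster merging needs at least 2 clusters")

  zero_var <- apply(sig, 2L, stats::sd) == 0
  r <- suppressWarnings(stats::cor(sig))
  if (any(zero_var)) {
    warning("zero-variance signature column(s): ",
            paste(colnames(sig)[zero_var], collapse = ", "),
            "; undefined correlations set to 0")
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  off <- r[upper.tri(r)]
  if (length(off) >= 2L) {
    rho_T <- mean(off) + rho_prime * stats::sd(off)
  } else {
    # single pair: sd undefined; only identical signatures may merge
    rho_T <- 1
  }

  B <- (r >= rho_T) * 1
  diag(B) <- 1
  dimnames(B) <- dimnames(r)

  if (sum(B) - K > 0) {
    part <- do.call(mcl, c(list(B = B), mcl_params))
  } else {
    part <- seq_len(K)
  }
  names(part) <- colnames(sig)

  # relabel merged ids in order of first appearance of their member clusters
  part <- stats::setNames(match(part, unique(part)), names(part))

  merged_cluster <- stats::setNames(
    part[as.character(x$cell_cluster[colnames(x$values)])],
    colnames(x$values))
  merged <- annotated_expression(x$values, merged_cluster, x$gene_cluster)
  merged_sig <- compute_signatures(merged, mode)
  provenance <- split(names(part), part)

  structure(list(
    r = r, rho_prime = rho_prime, rho_T = rho_T, B = B,
    partition = part, signatures = merged_sig, mode = mode,
    provenance = provenance, merged_expression = merged
  ), class = "merge_decision")
}

#' @exportS3Method base::print
print.merge_decision <- function(x, ...) {
  cat(sprintf("merge_decision: %d clusters -> %d merged (rho' = %g, rho_T = %.4f)\n",
              length(x$partition), ncol(x$signatures), x$rho_prime, x$rho_T))
  invisible(x)
}

#' Merge-partition sweep over candidate rho_prime values
#'
#' Recomputes the binary correlation matrix and merge partition for a grid of
#' `rho_prime` values, the programmatic equivalent of inspecting a series of
#' binarized cluster-similarity heatmaps before committing to a threshold.
#'
#' @param x An [annotated_expression()].
#' @param rho_grid Candidate values.
#' @param mode Passed to [compute_signatures()].
#' @return Data frame: rho_prime, rho_T, n_merged, partition (comma-separated
#'   merged ids in original-cluster order).
#' @export
sweep_rho_prime <- function(x, rho_grid = seq(0.5, 1.5, by = 0.1),
                            mode = "centroid") {
  rows <- lapply(rho_grid, function(rp) {
    md <- merge_clusters(x, rho_prime = rp, mode = mode)
    data.frame(rho_prime = rp, rho_T = md$rho_T,
               n_merged = ncol(md$signatures),
               partition = paste(md$partition, collapse = ","))
  })
  do.call(rbind, rows)
}
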