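#' Remove step: flag putative doublets by DCP similarity
#'
#' Compares every cell's DCP to (1) the DCP of each merged reference centroid
#' and (2) the mean DCP of each synthetic doublet set. Similarity is Pearson
#' correlation when there are more than 2 merged references and negative
#' Euclidean distance when there are exactly 2 (length-2 DCPs make Pearson
#' degenerate at +/-1). A cell whose most similar candidate is a synthetic set
#' becomes a putative doublet; exact ties are resolved toward the singlet
#' (reference) candidate.
#'
#' @param cell_dcps Cells x n DCP matrix ([dcp_table()] on the real cells).
#' @param reference_dcps n_ref x n DCP matrix of the reference centroids
#'   (rows named by merged cluster id).
#' @param synthetic_dcps Sets x n matrix of synthetic-set mean DCPs
#'   ([synthetic_mean_dcps()]), rows named `"a|b.class"`.
#' @param original_cluster Named vector cell -> original (merged) cluster id.
#' @return Object of class `doublet_calls`: data frame `table` with columns
#'   cell, original_cluster, best_match, similarity, is_putative_doublet, and
#'   `state` (per-cell `"singlet"` / `"putative_doublet"`).
#' @export
remove_step <- function(cell_dcps, reference_dcps, synthetic_dcps,
                        original_cluster) {
  cell_dcps <- as.matrix(cell_dcps)
  n <- ncol(cell_dcps)
  if (is.null(synthetic_dcps) || nrow(synthetic_dcps) == 0L) {
    stop("synthetic mean DCPs must be non-empty")
  }
  cand <- rbind(as.matrix(reference_dcps), as.matrix(synthetic_dcps))
  n_ref <- nrow(reference_dcps)
  if (n > 2L) {
    sim <- suppressWarnings(stats::cor(t(cell_dcps), t(cand)))
    if (anyNA(sim)) {
      warning("constant DCP vector(s): undefined Pearson similarity treated as -Inf")
      sim[is.na(sim)] <- -Inf
    }
  } else {
    d2 <- outer(rowSums(cell_dcps^2), rep(1, nrow(cand))) +
      outer(rep(1, nrow(cell_dcps)), rowSums(cand^2)) -
      2 * cell_dcps %*% t(cand)
    sim <- -sqrt(pmax(d2, 0))
  }
  # candidate columns are references first, so exact ties favour singlet
  best <- max.col(sim, ties.method = "first")
  best_match <- rownames(cand)[best]
  is_doub <- best > n_ref
  cells <- rownames(cell_dcps)
  tab <- data.frame(
    cell = cells,
    original_cluster = as.character(original_cluster[cells]),
    best_match = best_match,
    similarity = sim[cbind(seq_along(best), best)],
    is_putative_doublet = is_doub,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 state = stats::setNames(
                   ifelse(is_doub, "putative_doublet", "singlet"), cells),
                 recluster_label = stats::setNames(rep(NA_character_,
                                                       length(cells)), cells)),
            class = "doublet_calls")
}

#' Recluster step: group putative doublets by top DCP contributors
#'
#' Each putative doublet is labelled by its two largest DCP components
#' (merged cluster ids, sorted ascending, joined `"a|b"`); when the 30/70
#' synthetic mode was used, the weight-class suffix of the cell's best-matching
#' synthetic set (`.even`, `.one` or `.two`) is appended for more granular
#' rescue. Putative doublets leave their original clusters; a DCP with a
#' single non-zero component takes the next-largest component (possibly zero)
#' with a lowest-id tie-break.
#'
#' @param calls A `doublet_calls` object from [remove_step()].
#' @param cell_dcps Cells x n DCP matrix used in the remove step.
#' @param only50 Whether synthetics were generated with `only50 = TRUE`
#'   (suppresses the weight-class suffix).
#' @return The `doublet_calls` object with `recluster_label` filled in for
#'   putative doublets.
#' @export
recluster_step <- function(calls, cell_dcps, only50 = FALSE) {
  stopifnot(inherits(calls, "doublet_calls"))
  cell_dcps <- as.matrix(cell_dcps)
  refs <- colnames(cell_dcps)
  doub <- calls$table$cell[calls$table$is_putative_doublet]
  ref_rank <- order(order_labels(refs))  # numeric-aware id order for tie-breaks
  for (cell in doub) {
    w <- cell_dcps[cell, ]
    ord <- order(-w, ref_rank)
    top <- refs[ord[1:2]]
    lab <- paste(order_labels(top), collapse = "|")
    if (!only50) {
      bm <- calls$table$best_match[calls$table$cell == cell]
      suffix <- sub("^.*\\.", "", bm)
      lab <- paste0(lab, ".", suffix)
    }
    calls$recluster_label[cell] <- lab
  }
  calls
}

#' One-way ANOVA and Tukey-Kramer tests from group aggregates
#'
#' Computes per-gene overall F statistics, p-values and Tukey-Kramer adjusted
#' pairwise p-values of a focus group against every other group, using only
#' the per-group sizes, total sums (TS) and sums of squares (TSS). This is
#' algebraically identical to the direct per-gene one-way ANOVA but needs a
#' single pass over the expression block.
#'
#' @param n Named vector of group sizes.
#' @param TS Genes x G matrix of per-group sums.
#' @param TSS Genes x G matrix of per-group sums of squares.
#' @param focus Name of the group contrasted against all others.
#' @return List: `F`, `p` (per gene), `tukey` (genes x other-groups matrix of
#'   adjusted p-values), `means` (genes x G), `df` (between, within).
#' @export
anova_from_aggregates <- function(n, TS, TSS, focus) {
  groups <- names(n)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(n < 1L)) stop("group sizes must be >= 1")
  if (!focus %in% groups) stop("unknown focus group: ", focus)
  N <- sum(n)
  G <- length(groups)
  df_between <- G - 1L
  df_within <- N - G
  S <- rowSums(TS)
  # rowSums (not %*%) keeps the reduction bitwise independent of block height
  ss_between <- rowSums(sweep(TS^2, 2L, n, "/")) - S^2 / N
  ss_total <- rowSums(TSS) - S^2 / N
  ss_within <- pmax(ss_total - ss_between, 0)
  ss_between <- pmax(ss_between, 0)
  if (df_within == 0L) {
    warning("zero within-group degrees of freedom: p-values undefined")
    Fv <- rep(NA_real_, nrow(TS))
    p <- rep(NA_real_, nrow(TS))
    tk <- matrix(NA_real_, nrow(TS), G - 1L)
  } else {
    msw <- as.vector(ss_within) / df_within
    msb <- as.vector(ss_between) / df_between
    Fv <- ifelse(msw == 0, ifelse(msb <= 1e-12, 0, Inf), msb / msw)
    p <- stats::pf(Fv, df_between, df_within, lower.tail = FALSE)
    means <- sweep(TS, 2L, n, "/")
    others <- setdiff(groups, focus)
    tk <- vapply(others, function(k) {
      diff <- abs(means[, focus] - means[, k])
      se <- sqrt((msw / 2) * (1 / n[[focus]] + 1 / n[[k]]))
      q <- ifelse(se == 0, ifelse(diff <= 1e-12, 0, Inf), diff / se)
      stats::ptukey(q, nmeans = G, df = df_within, lower.tail = FALSE)
    }, numeric(nrow(TS)))
    tk <- matrix(tk, nrow = nrow(TS), dimnames = list(rownames(TS), others))
  }
  means <- sweep(TS, 2L, n, "/")
  list(F = as.vector(Fv), p = as.vector(p), tukey = tk, means = means,
       df = c(between = df_between, within = df_within))
}

#' Chunked one-way ANOVA over an expression block
#'
#' Splits the gene axis into fixed-size chunks (1,000 genes by convention),
#' reduces each chunk to per-group sizes, sums and sums of squares, and calls
#' [anova_from_aggregates()]. Results are bitwise independent of the chunk
#' boundaries, so the block size only bounds memory use.
#'
#' @param values Genes x cells numeric matrix.
#' @param groups Per-cell group labels (vector or factor, length `ncol(values)`).
#' @param focus Group contrasted against all others in the Tukey tests.
#' @param chunk_size Genes per chunk.
#' @return As [anova_from_aggregates()], with rows in `values` order.
#' @export
chunked_anova <- function(values, groups, focus, chunk_size = 1000L) {
  values <- as.matrix(values)
  groups <- factor(groups)
  stopifnot(length(groups) == ncol(values))
  n <- stats::setNames(as.vector(table(groups)), levels(groups))
  chunks <- split(seq_len(nrow(values)),
                  ceiling(seq_len(nrow(values)) / chunk_size))
  parts <- lapply(chunks, function(idx) {
    X <- values[idx, , drop = FALSE]
    TS <- t(rowsum(t(X), groups))
    TSS <- t(rowsum(t(X)^2, groups))
    anova_from_aggregates(n, TS, TSS, focus)
  })
  list(
    F = unlist(lapply(parts, `[[`, "F"), use.names = FALSE),
    p = unlist(lapply(parts, `[[`, "p"), use.names = FALSE),
    tukey = do.call(rbind, lapply(parts, `[[`, "tukey")),
    means = do.call(rbind, lapply(parts, `[[`, "means")),
    df = parts[[1L]]$df
  )
}

#' Uniquely expressed genes of a doublet cluster
#'
#' A gene is uniquely expressed in a candidate doublet cluster when (1) the
#' overall one-way ANOVA across the doublet cluster and all retained reference
#' clusters has p <= `alpha`, (2) every Tukey-adjusted pairwise comparison of
#' the doublet cluster against each reference cluster has p <= `alpha`, and
#' (3) the doublet cluster has strictly higher mean expression than every
#' reference cluster. Genes with zero variance across all groups cannot
#' satisfy these conditions and are excluded.
#'
#' @param values Genes x cells expression matrix.
#' @param z_cells Cells of the candidate doublet cluster.
#' @param ref_groups Named list: retained reference cluster -> member cells.
#' @param alpha Significance level for both tests (0.05 by the method's
#'   definition).
#' @param chunk_size Passed to [chunked_anova()].
#' @return Character vector of uniquely expressed gene names.
#' @export
unique_genes <- function(values, z_cells, ref_groups, alpha = 0.05,
                         chunk_size = 1000L) {
  if (!length(z_cells) || any(lengths(ref_groups) == 0L)) {
    stop("doublet cluster and every reference cluster must be non-empty")
  }
  cells <- c(z_cells, unlist(ref_groups, use.names = FALSE))
  groups <- c(rep(".Z", length(z_cells)),
              rep(names(ref_groups), lengths(ref_groups)))
  X <- values[, cells, drop = FALSE]
  res <- chunked_anova(X, groups, focus = ".Z", chunk_size = chunk_size)
  ok_overall <- !is.na(res$p) & res$p <= alpha
  ok_tukey <- rowSums(res$tukey <= alpha, na.rm = TRUE) == ncol(res$tukey) &
    !apply(is.na(res$tukey), 1L, any)
  higher <- res$means[, ".Z"] > apply(res$means[, colnames(res$tukey),
                                               drop = FALSE], 1L, max)
  rownames(values)[ok_overall & ok_tukey & higher]
}

#' Rescue step: return unique-gene doublet clusters to singlet status
#'
#' Counts uniquely expressed genes for every reclustered doublet cluster
#' against the post-removal reference clusters. Clusters reaching at least
#' `U` unique genes are rescued whole: every member becomes a
#' `rescued_singlet` and rejoins its original cluster; all other putative
#' doublets become `final_doublet`. Conventional thresholds are `U = 4` when
#' testing marker genes only and `U = 30` with the full gene list.
#'
#' @param calls A `doublet_calls` object after [recluster_step()].
#' @param x An [annotated_expression()] carrying the expression used for the
#'   unique-gene tests (the marker object, or the full matrix).
#' @param U Minimum number of unique genes for rescue (>= 0).
#' @param alpha Significance level of the unique-gene tests.
#' @param chunk_size Passed to [chunked_anova()].
#' @return List: `calls` (final `doublet_calls`, states in
#'   singlet/rescued_singlet/final_doublet) and `report` (data frame per
#'   doublet cluster: label, size, unique-gene count, threshold, decision,
#'   comma-separated unique genes).
#' @export
rescue_step <- function(calls, x, U = 4, alpha = 0.05, chunk_size = 1000L) {
  stopifnot(inherits(calls, "doublet_calls"), inherits(x, "annotated_expression"))
  if (U < 0) stop("U must be >= 0")
  tab <- calls$table
  doub_cells <- tab$cell[tab$is_putative_doublet]
  singlet_cells <- tab$cell[!tab$is_putative_doublet]
  if (!length(doub_cells)) {
    return(list(calls = calls,
                report = data.frame(label = character(0), size = integer(0),
                                    unique_gene_count = integer(0),
                                    threshold = numeric(0),
                                    decision = character(0),
                                    unique_genes = character(0))))
  }
  orig <- stats::setNames(tab$original_cluster, tab$cell)
  ref_groups <- split(singlet_cells, orig[singlet_cells])
  zs <- split(doub_cells, calls$recluster_label[doub_cells])
  report <- do.call(rbind, lapply(names(zs), function(lab) {
    ug <- unique_genes(x$values, zs[[lab]], ref_groups, alpha = alpha,
                       chunk_size = chunk_size)
    data.frame(label = lab, size = length(zs[[lab]]),
               unique_gene_count = length(ug), threshold = U,
               decision = if (length(ug) >= U) "rescued" else "doublet",
               unique_genes = paste(ug, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rescued_labels <- report$label[report$decision == "rescued"]
  for (cell in doub_cells) {
    calls$state[cell] <- if (calls$recluster_label[cell] %in% rescued_labels) {
      "rescued_singlet"
    } else "final_doublet"
  }
  list(calls = calls, report = report)
}

#' Final per-cell labels of a call set
#'
#' Singlets and rescued singlets carry their original cluster id; final
#' doublets carry their recluster label.
#'
#' @param calls A finalized `doublet_calls` object.
#' @return Data frame: cell, label, state.
#' @export
final_labels <- function(calls) {
  tab <- calls$table
  lab <- ifelse(calls$state[tab$cell] == "final_doublet",
                calls$recluster_label[tab$cell], tab$original_cluster)
  data.frame(cell = tab$cell, label = lab,
             state = unname(calls$state[tab$cell]), stringsAsFactors = FALSE)
}

#' @exportS3Method base::print
print.doublet_calls <- function(x, ...) {
  cat("doublet_calls:", paste(sprintf("%s=%d", names(table(x$state)),
                                      as.vector(table(x$state))), collapse = ", "),
      "\n")
  invisible(x)
}
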