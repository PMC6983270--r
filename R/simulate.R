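#' Parameters for the ground-truth fixture simulator
#'
#' Defines a cluster-structured log-normalized expression dataset with
#' disjoint marker-gene blocks, optional spiked doublets and an optional
#' transitional population, so every pipeline stage can be exercised against
#' known truth without any download.
#'
#' Each singlet expresses its cluster's marker block at
#' `marker_effect * activity` plus Gaussian noise (truncated at zero), where
#' `activity` is a per-cell lognormal transcriptional-activity factor —
#' the analogue of cell-to-cell RNA-content differences that make real
#' doublets contribute unequally. Heterotypic doublets mix two singlets from
#' distinct clusters (each parent keeping its own activity), homotypic
#' doublets mix two singlets of one cluster, and transitional cells express
#' both parent programs evenly under a single shared activity factor plus
#' `n_unique_genes` genes expressed nowhere else.
#'
#' @param n_clusters Number of singlet clusters (>= 1).
#' @param cells_per_cluster Singlets per cluster.
#' @param n_marker_genes_per_cluster Marker genes in each cluster's block.
#' @param n_background_genes Non-discriminating genes (full matrix only).
#' @param marker_effect Mean log-expression lift of a cluster's markers.
#' @param noise_sd Gaussian noise sd in log space.
#' @param baseline Mean log expression of inactive genes.
#' @param activity_sd sd of the per-cell log activity factor.
#' @param doublet_rate Spiked doublets as a fraction of the singlet count.
#' @param prob_even Probability a spiked doublet is an even 50/50 mix; the
#'   rest are 30/70 or 70/30 with equal chance.
#' @param homotypic_fraction Fraction of spiked doublets drawn within one
#'   cluster.
#' @param mix_space `"count"` (default) mixes parents on the molecule scale
#'   (`2^x - 1`, then re-logged), the way a physical doublet combines two
#'   transcriptomes; `"log"` averages log values directly, matching the
#'   detector's own synthetic construction.
#' @param transitional If `TRUE`, add a transitional population between
#'   clusters 1 and 2.
#' @param transitional_cells Size of that population.
#' @param n_unique_genes Genes expressed exclusively in the transitional
#'   population.
#' @param seed RNG seed; the fixture is byte-identical given the seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_clusters = 2, cells_per_cluster = 500,
                              n_marker_genes_per_cluster = 50,
                              n_background_genes = 200,
                              marker_effect = 3.0, noise_sd = 0.5,
                              baseline = 0.2, activity_sd = 0.2,
                              doublet_rate = 0.1, prob_even = 1.0,
                              homotypic_fraction = 0,
                              mix_space = c("count", "log"),
                              transitional = FALSE, transitional_cells = 50,
                              n_unique_genes = 10, seed = 7L) {
  p <- list(n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
            n_marker_genes_per_cluster = n_marker_genes_per_cluster,
            n_background_genes = n_background_genes,
            marker_effect = marker_effect, noise_sd = noise_sd,
            baseline = baseline, activity_sd = activity_sd,
            doublet_rate = doublet_rate, prob_even = prob_even,
            homotypic_fraction = homotypic_fraction,
            mix_space = match.arg(mix_space),
            transitional = transitional,
            transitional_cells = transitional_cells,
            n_unique_genes = n_unique_genes, seed = as.integer(seed))
  rates <- c(doublet_rate = doublet_rate, prob_even = prob_even,
             homotypic_fraction = homotypic_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  counts <- c(n_clusters, cells_per_cluster, n_marker_genes_per_cluster)
  if (any(counts < 1)) stop("counts must be positive")
  if (doublet_rate > 0 && homotypic_fraction < 1 && n_clusters < 2) {
    stop("heterotypic doublets require at least 2 clusters")
  }
  structure(p, class = "simulation_params")
}

#' Simulate a ground-truth clustered expression fixture
#'
#' @param params A [simulation_params()] object.
#' @return List: `marker` ([annotated_expression()] over marker and unique
#'   genes, cluster-contiguous cell order, gene clusters set), `full`
#'   (`annotated_expression` adding the background genes), `truth` (data
#'   frame: cell, type in singlet/heterotypic_doublet/homotypic_doublet/
#'   transitional, parent_a, parent_b), and `params`.
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  with_preserved_rng({
    set.seed(p$seed)
    K <- p$n_clusters
    marker_genes <- unlist(lapply(seq_len(K), function(k)
      sprintf("mk%d.%d", k, seq_len(p$n_marker_genes_per_cluster))))
    uniq_genes <- if (p$transitional && p$n_unique_genes > 0) {
      sprintf("uq.%d", seq_len(p$n_unique_genes))
    } else character(0)
    bg_genes <- if (p$n_background_genes > 0) {
      sprintf("bg.%d", seq_len(p$n_background_genes))
    } else character(0)
    genes <- c(marker_genes, uniq_genes, bg_genes)
    gene_block <- rep(seq_len(K), each = p$n_marker_genes_per_cluster)

    base_profile <- function() pmax(0, p$baseline + stats::rnorm(length(genes), 0, p$noise_sd))
    singlet <- function(k) {
      v <- base_profile()
      off <- which(gene_block != k)   # marker genes sit first in the gene axis
      v[off] <- pmax(0, p$baseline / 2 + stats::rnorm(length(off), 0, p$noise_sd / 2))
      act <- exp(stats::rnorm(1, 0, p$activity_sd))
      own <- which(gene_block == k)
      v[own] <- pmax(0, p$marker_effect * act + stats::rnorm(length(own), 0, p$noise_sd))
      if (length(uniq_genes)) v[length(marker_genes) + seq_along(uniq_genes)] <- 0
      v
    }

    n_singlets <- K * p$cells_per_cluster
    singlet_cluster <- rep(seq_len(K), each = p$cells_per_cluster)
    singlet_mat <- vapply(singlet_cluster, singlet, numeric(length(genes)))
    singlet_ids <- sprintf("c%d.%d", singlet_cluster,
                           unlist(lapply(seq_len(K), function(k)
                             seq_len(p$cells_per_cluster))))
    colnames(singlet_mat) <- singlet_ids

    mix <- function(a, b, w) {
      if (p$mix_space == "log") {
        w * a + (1 - w) * b
      } else {
        log2(w * (2^a - 1) + (1 - w) * (2^b - 1) + 1)
      }
    }

    n_doub <- round(p$doublet_rate * n_singlets)
    doub_mat <- NULL; doub_cluster <- integer(0)
    doub_type <- character(0); doub_pa <- character(0); doub_pb <- character(0)
    if (n_doub > 0) {
      n_homo <- round(p$homotypic_fraction * n_doub)
      cols <- vector("list", n_doub)
      for (i in seq_len(n_doub)) {
        homo <- i <= n_homo
        if (homo) {
          ka <- kb <- sample(K, 1L)
        } else {
          kk <- sample(K, 2L)
          ka <- kk[1L]; kb <- kk[2L]
        }
        pa <- sample(singlet_ids[singlet_cluster == ka], 1L)
        pb <- sample(singlet_ids[singlet_cluster == kb], 1L)
        w <- if (stats::runif(1) < p$prob_even) 0.5 else sample(c(0.3, 0.7), 1L)
        cols[[i]] <- mix(singlet_mat[, pa], singlet_mat[, pb], w)
        doub_cluster[i] <- if (stats::runif(1) < 0.5) ka else kb
        doub_type[i] <- if (homo) "homotypic_doublet" else "heterotypic_doublet"
        doub_pa[i] <- pa; doub_pb[i] <- pb
      }
      doub_mat <- do.call(cbind, cols)
      colnames(doub_mat) <- sprintf("d.%d", seq_len(n_doub))
    }

    trans_mat <- NULL
    if (p$transitional) {
      if (K < 2L) stop("a transitional population requires at least 2 clusters")
      tcols <- vapply(seq_len(p$transitional_cells), function(i) {
        act <- exp(stats::rnorm(1, 0, p$activity_sd))
        v <- base_profile()
        idx12 <- which(gene_block %in% c(1L, 2L))
        v[idx12] <- pmax(0, 0.5 * p$marker_effect * act +
                           stats::rnorm(length(idx12), 0, p$noise_sd))
        if (K > 2L) {
          rest <- which(!gene_block %in% c(1L, 2L))
          v[rest] <- pmax(0, p$baseline / 2 + stats::rnorm(length(rest), 0, p$noise_sd / 2))
        }
        v[length(marker_genes) + seq_len(p$n_unique_genes)] <-
          pmax(0, p$marker_effect * act + stats::rnorm(p$n_unique_genes, 0, p$noise_sd))
        v
      }, numeric(length(genes)))
      trans_mat <- matrix(tcols, nrow = length(genes))
      colnames(trans_mat) <- sprintf("t.%d", seq_len(p$transitional_cells))
    }

    values <- cbind(singlet_mat, doub_mat, trans_mat)
    rownames(values) <- genes
    cluster <- c(singlet_cluster, doub_cluster,
                 rep(1L, if (is.null(trans_mat)) 0L else ncol(trans_mat)))
    names(cluster) <- colnames(values)

    # cluster-contiguous cell order (stable within cluster)
    ord <- order(cluster, method = "radix")
    values <- values[, ord, drop = FALSE]
    cluster <- cluster[ord]

    truth <- data.frame(
      cell = c(singlet_ids, colnames(doub_mat) %||% character(0),
               colnames(trans_mat) %||% character(0)),
      type = c(rep("singlet", n_singlets), doub_type,
               rep("transitional", if (is.null(trans_mat)) 0L else ncol(trans_mat))),
      parent_a = c(rep(NA_character_, n_singlets), doub_pa,
                   rep("c1", if (is.null(trans_mat)) 0L else ncol(trans_mat))),
      parent_b = c(rep(NA_character_, n_singlets), doub_pb,
                   rep("c2", if (is.null(trans_mat)) 0L else ncol(trans_mat))),
      stringsAsFactors = FALSE
    )
    truth <- truth[match(colnames(values), truth$cell), ]
    rownames(truth) <- NULL

    gene_cluster <- c(gene_block,
                      rep(K + 1L, length(uniq_genes)),
                      rep(K + 2L, length(bg_genes)))
    names(gene_cluster) <- genes

    marker_names <- c(marker_genes, uniq_genes)
    marker <- annotated_expression(values[marker_names, , drop = FALSE], cluster,
                                   gene_cluster[marker_names])
    full <- annotated_expression(values, cluster, gene_cluster)
    list(marker = marker, full = full, truth = truth, params = p)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
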