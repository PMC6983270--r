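#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run with the conventional
#' defaults: `rhop = 1`, 30/70 synthetics (`only50 = FALSE`), 100 synthetic
#' doublets per set, rescue threshold `min_uniq = 4` (30 when scanning the
#' full gene list), centroid references, no cell-cycle removal, one run.
#'
#' @param expression Either an [annotated_expression()] (in-memory input) or
#'   a path to a clustered marker expression file (with `groups`).
#' @param groups Groups file path (ignored for in-memory input).
#' @param full Optional full-matrix input: an `annotated_expression` or a
#'   path (see [read_icgs()]).
#' @param rhop Cluster-merge threshold scaling rho'.
#' @param only50 Use only even 50/50 synthetic doublets.
#' @param num_doubs Synthetic doublets per set.
#' @param min_uniq Unique genes needed to rescue a doublet cluster; defaults
#'   to 4, or 30 when `use_full = TRUE`.
#' @param use_full Scan the full gene list (not only markers) in the rescue
#'   step; requires `full`.
#' @param mode `"centroid"` or `"medoid"` references.
#' @param remove_cc Remove cell-cycle-associated gene clusters first.
#' @param species Species for the bundled cell-cycle set (`"Hs"`/`"Mm"`).
#' @param cc_gmt Optional GMT path overriding the bundled cell-cycle set.
#' @param scale_mode Deconvolution scaling, see [solve_dcp()].
#' @param seed Global seed; run `r` of `n_runs` uses `seed + r - 1` for
#'   synthetic sampling, so single runs and consensus runs are reproducible
#'   independently.
#' @param n_runs Number of repeated runs; with `n_runs > 1` the consensus
#'   doublet set (cells called in every run) is also produced.
#' @param output_dir Directory for the tabular outputs (`NULL` = don't write).
#' @param mcl_params Named list of [mcl()] overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, groups = NULL, full = NULL,
                       rhop = 1.0, only50 = FALSE, num_doubs = 100,
                       min_uniq = NULL, use_full = FALSE,
                       mode = c("centroid", "medoid"),
                       remove_cc = FALSE, species = "Hs", cc_gmt = NULL,
                       scale_mode = "none", seed = 1L, n_runs = 1L,
                       output_dir = NULL, mcl_params = list()) {
  if (is.null(min_uniq)) min_uniq <- if (use_full) 30 else 4
  if (use_full && is.null(full)) stop("use_full = TRUE requires a full matrix")
  structure(list(expression = expression, groups = groups, full = full,
                 rhop = rhop, only50 = only50, num_doubs = num_doubs,
                 min_uniq = min_uniq, use_full = use_full,
                 mode = match.arg(mode), remove_cc = remove_cc,
                 species = species, cc_gmt = cc_gmt, scale_mode = scale_mode,
                 seed = as.integer(seed), n_runs = as.integer(n_runs),
                 output_dir = output_dir, mcl_params = mcl_params),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full doublet-detection pipeline
#'
#' Executes preprocess (label standardization, optional cell-cycle removal),
#' cluster merging, synthetic doublet generation, deconvolution, and the
#' remove / recluster / rescue sequence; optionally repeats the stochastic
#' stages `n_runs` times and intersects the per-run doublet sets into a
#' consensus. Tabular outputs (from the first run) are written when
#' `output_dir` is set; partial outputs are removed if a stage fails.
#'
#' @param config A [run_config()].
#' @return Object of class `pipeline_result`: `bundle` ([output_bundle()] of
#'   the first run), `calls` (final `doublet_calls`), `rescue_report`,
#'   `merge` (the `merge_decision`), `cell_dcps`, `run_doublet_sets` (per-run
#'   final doublet cells), `consensus` (cells called in all runs; equals the
#'   single run's set when `n_runs = 1`), and `log` (parameters, rho_T,
#'   merge map, per-stage counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config

  inputs <- with_stage("input", {
    if (inherits(cfg$expression, "annotated_expression")) {
      full <- cfg$full
      if (!is.null(full) && !inherits(full, "annotated_expression")) {
        stop("in-memory runs need an in-memory full matrix")
      }
      list(marker = cfg$expression, full = full)
    } else {
      read_icgs(cfg$expression, cfg$groups, cfg$full)
    }
  })

  std <- with_stage("preprocess", standardize_labels(inputs$marker))
  marker <- std$expression
  full <- inputs$full
  if (!is.null(full)) {
    full <- annotated_expression(full$values, marker$cell_cluster[colnames(full$values)])
  }

  cc_report <- NULL
  if (isTRUE(cfg$remove_cc)) {
    cc <- with_stage("preprocess", {
      sets <- if (is.null(cfg$cc_gmt)) cell_cycle_sets(cfg$species) else read_gmt(cfg$cc_gmt)
      remove_cell_cycle(marker, sets)
    })
    marker <- cc$expression
    cc_report <- cc$report
    if (!is.null(full) && length(cc$removed_genes)) {
      keep <- setdiff(rownames(full$values), cc$removed_genes)
      full <- subset_expression(full, genes = keep)
    }
  }

  merge <- with_stage("merge", merge_clusters(marker, rho_prime = cfg$rhop,
                                              mode = cfg$mode,
                                              mcl_params = cfg$mcl_params))
  merged <- merge$merged_expression
  sig <- merge$signatures

  cell_dcps <- with_stage("deconvolution",
                          dcp_table(merged, sig, scale_mode = cfg$scale_mode))
  ref_dcps <- with_stage("deconvolution",
                         dcp_table(sig, sig, scale_mode = cfg$scale_mode))

  rescue_expr <- if (cfg$use_full) {
    annotated_expression(full$values, merged$cell_cluster[colnames(full$values)])
  } else merged

  one_run <- function(run_seed) {
    syn <- with_stage("synthetics",
                      generate_synthetics(merged, num_doubs = cfg$num_doubs,
                                          only50 = cfg$only50, seed = run_seed))
    syn_dcps <- with_stage("deconvolution",
                           dcp_table(syn, sig, scale_mode = cfg$scale_mode))
    syn_mean <- synthetic_mean_dcps(syn_dcps, syn$set)
    calls <- with_stage("remove",
                        remove_step(cell_dcps, ref_dcps, syn_mean,
                                    merged$cell_cluster))
    calls <- with_stage("recluster",
                        recluster_step(calls, cell_dcps, only50 = cfg$only50))
    res <- with_stage("rescue",
                      rescue_step(calls, rescue_expr, U = cfg$min_uniq))
    list(calls = res$calls, report = res$report, syn = syn, syn_dcps = syn_dcps)
  }

  runs <- lapply(seq_len(cfg$n_runs), function(r) one_run(cfg$seed + r - 1L))
  run_sets <- lapply(runs, function(r) {
    r$calls$table$cell[r$calls$state[r$calls$table$cell] == "final_doublet"]
  })
  consensus <- Reduce(intersect, run_sets)

  first <- runs[[1L]]
  finals <- final_labels(first$calls)
  doub <- finals[finals$state == "final_doublet", , drop = FALSE]
  nondoub <- finals[finals$state != "final_doublet", , drop = FALSE]
  bundle <- output_bundle(
    drs_doublet_table = first$calls$table,
    drs_results = cell_dcps,
    final_doublets_groups = doub,
    final_nondoublets_groups = nondoub,
    final_doublets_exp = merged$values[, doub$cell, drop = FALSE],
    final_nondoublets_exp = merged$values[, nondoub$cell, drop = FALSE],
    synthetic_dcps = first$syn_dcps
  )

  log <- list(
    parameters = cfg[c("rhop", "only50", "num_doubs", "min_uniq", "use_full",
                       "mode", "remove_cc", "scale_mode", "seed", "n_runs")],
    rho_T = merge$rho_T,
    merge_partition = merge$partition,
    n_cells = ncol(marker$values),
    n_merged_clusters = ncol(sig),
    n_putative_doublets = sum(first$calls$table$is_putative_doublet),
    n_rescued = sum(first$calls$state == "rescued_singlet"),
    n_final_doublets = nrow(doub),
    n_consensus_doublets = length(consensus),
    cell_cycle = cc_report
  )

  if (!is.null(cfg$output_dir)) {
    written <- character(0)
    tryCatch({
      written <- write_outputs(bundle, cfg$output_dir)
      if (cfg$n_runs > 1L) {
        cp <- file.path(cfg$output_dir, "Consensus_doublets.txt")
        writeLines(consensus, cp)
        written <- c(written, cp)
      }
      lp <- file.path(cfg$output_dir, "run.log")
      writeLines(format_run_log(log), lp)
    }, error = function(e) {
      unlink(written)
      stop(sprintf("[stage output] %s", conditionMessage(e)), call. = FALSE)
    })
  }

  structure(list(bundle = bundle, calls = first$calls,
                 rescue_report = first$report, merge = merge,
                 cell_dcps = cell_dcps, run_doublet_sets = run_sets,
                 consensus = consensus, log = log, config = cfg),
            class = "pipeline_result")
}

format_run_log <- function(log) {
  pars <- vapply(log$parameters, function(v) paste(format(v), collapse = ","),
                 character(1))
  c(sprintf("param %s = %s", names(pars), pars),
    sprintf("rho_T = %.6f", log$rho_T),
    sprintf("merge %s -> %d", names(log$merge_partition), log$merge_partition),
    sprintf("cells = %d", log$n_cells),
    sprintf("merged_clusters = %d", log$n_merged_clusters),
    sprintf("putative_doublets = %d", log$n_putative_doublets),
    sprintf("rescued_singlets = %d", log$n_rescued),
    sprintf("final_doublets = %d", log$n_final_doublets),
    sprintf("consensus_doublets = %d", log$n_consensus_doublets))
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("pipeline_result: %d cells, %d merged clusters, ",
                     "%d putative -> %d final doublets (%d rescued)\n"),
              x$log$n_cells, x$log$n_merged_clusters,
              x$log$n_putative_doublets, x$log$n_final_doublets,
              x$log$n_rescued))
  invisible(x)
}
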