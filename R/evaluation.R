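#' Performance metrics from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative counts of true/false positives/negatives
#'   (positives = doublet calls).
#' @return One-row data frame: TP, FP, TN, FN, sensitivity and specificity (in
#'   percent), f1 (fraction). Sensitivity is `NA` when no positives exist in
#'   truth. Values are full precision; see [round_half_up()] for display.
#' @export
performance_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  data.frame(
    TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  )
}

#' Score doublet calls against known truth
#'
#' @param calls Character vector of cells called doublets.
#' @param truth_doublets Character vector of cells known to be doublets.
#' @param universe All evaluated cells (calls and truth must lie within it).
#' @param exclude Cells removed before counting (e.g. ambiguous barcodes).
#' @return As [performance_from_counts()].
#' @export
confusion <- function(calls, truth_doublets, universe, exclude = NULL) {
  if (!all(calls %in% universe) || !all(truth_doublets %in% universe)) {
    stop("calls and truth must be defined over the supplied cell universe")
  }
  universe <- setdiff(universe, exclude)
  calls <- intersect(calls, universe)
  truth_doublets <- intersect(truth_doublets, universe)
  tp <- length(intersect(calls, truth_doublets))
  fp <- length(setdiff(calls, truth_doublets))
  fn <- length(setdiff(truth_doublets, calls))
  tn <- length(universe) - tp - fp - fn
  performance_from_counts(tp, fp, tn, fn)
}

#' Combine doublet call sets from several callers
#'
#' @param call_sets List (>= 2) of character vectors of called cells, all over
#'   the same universe.
#' @param mode `"union"` (called by any; favours sensitivity) or
#'   `"intersection"` (called by all; favours specificity).
#' @param universe Optional universe for validation.
#' @return Character vector of combined calls.
#' @export
combine_calls <- function(call_sets, mode = c("union", "intersection"),
                          universe = NULL) {
  mode <- match.arg(mode)
  if (length(call_sets) < 2L) stop("need at least 2 call sets")
  if (!is.null(universe)) {
    bad <- !vapply(call_sets, function(s) all(s %in% universe), logical(1))
    if (any(bad)) stop("call set(s) outside the universe: ",
                       paste(which(bad), collapse = ", "))
  }
  Reduce(if (mode == "union") union else intersect, call_sets)
}

#' Consensus doublet set over repeated runs
#'
#' Cells called in every one of `N` runs; the intersection can only drop
#' false positives, so consensus specificity is never below a single run's.
#'
#' @param run_call_sets List of per-run called-cell vectors.
#' @param N Number of runs (defaults to `length(run_call_sets)`; must match).
#' @return Character vector of consensus calls.
#' @export
consensus_runs <- function(run_call_sets, N = length(run_call_sets)) {
  if (N == 0L || length(run_call_sets) == 0L) stop("no runs supplied")
  if (N != length(run_call_sets)) stop("N must equal the number of runs supplied")
  Reduce(intersect, run_call_sets)
}

#' Half-up rounding for display
#'
#' Rounds away from zero on exact halves (the convention of printed
#' performance tables), unlike `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Published PBMC doublet-caller benchmark counts
#'
#' Loads the shipped table of published confusion counts (TP/FP/TN/FN) and
#' printed sensitivity/specificity/F1 for doublet callers and their
#' union/intersection/consensus combinations on two experimentally annotated
#' PBMC datasets (genetic demultiplexing and cell hashing truth). Printed
#' metric columns are kept as character to preserve the published precision.
#'
#' @return Data frame: dataset, tool, combination, TP, FP, TN, FN,
#'   sensitivity, specificity, f1.
#' @export
caller_benchmark <- function() {
  path <- system.file("extdata", "pbmc_caller_benchmark.tsv",
                      package = "decondoublet", mustWork = TRUE)
  utils::read.delim(path, colClasses = c(rep("character", 3), rep("integer", 4),
                                         rep("character", 3)))
}

#' Published benchmark dataset sizes and doublet counts
#'
#' Barcode and known-doublet totals of the experimentally annotated benchmark
#' datasets after the published expressed-gene filters, plus the reported
#' heterotypic doublet-rate estimate used for the 8/7 whole-rate adjustment.
#'
#' @return Data frame: dataset, n_barcodes, n_doublets.
#' @export
benchmark_dataset_counts <- function() {
  path <- system.file("extdata", "pbmc_dataset_counts.tsv",
                      package = "decondoublet", mustWork = TRUE)
  utils::read.delim(path, colClasses = c("character", "integer", "integer"))
}

#' Doublet rate in percent
#'
#' @param n_doublets,n_cells Counts.
#' @return `100 * n_doublets / n_cells`.
#' @export
doublet_rate <- function(n_doublets, n_cells) 100 * n_doublets / n_cells

#' Adjust a heterotypic doublet rate to a whole-population rate
#'
#' Demultiplexing by donor genotype only detects doublets formed across
#' donors; with `k` equally represented donors a fraction `(k-1)/k` of
#' doublets is visible, so the whole rate is the observed rate times
#' `k/(k-1)` (8/7 for eight donors).
#'
#' @param rate Observed heterotypic (cross-donor) rate, percent.
#' @param n_donors Number of equally loaded donors.
#' @return Adjusted rate, percent.
#' @export
adjusted_doublet_rate <- function(rate, n_donors = 8) {
  rate * n_donors / (n_donors - 1)
}
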