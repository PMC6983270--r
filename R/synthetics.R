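#' Generate weighted synthetic doublet profiles
#'
#' For every unordered pair of merged reference clusters, samples member cells
#' uniformly with replacement and averages their expression to form synthetic
#' doublet profiles: an even 50/50 mix and, unless `only50`, additional 70/30
#' and 30/70 weighted mixes ("one" and "two"). Mixing happens in the provided
#' value space (log-normalized expression), so every synthetic profile lies
#' gene-wise between its two parent cells.
#'
#' For datasets beyond ~1000 cells a practical choice for `num_doubs` is about
#' 10% of the cell count; the conventional default is 100 per set.
#'
#' @param x An [annotated_expression()] whose cell clusters are the *merged*
#'   cluster ids (see [merge_clusters()]).
#' @param num_doubs Profiles per (pair, weight class) set.
#' @param only50 If `TRUE`, generate only the even 50/50 sets.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return Object of class `synthetic_doublets`: `profiles` (genes x m
#'   matrix), `pair` (m x 2 matrix of cluster ids, first < second),
#'   `weight_class` (factor: even/one/two), `set` (per-profile set label
#'   `"a|b.class"`), `seed`.
#' @export
generate_synthetics <- function(x, num_doubs = 100, only50 = FALSE, seed = 1L) {
  stopifnot(inherits(x, "annotated_expression"))
  if (num_doubs < 1) stop("num_doubs must be >= 1")
  cl <- cluster_cells(x)
  if (length(cl) < 2L) stop("need at least 2 merged clusters")
  if (any(lengths(cl) == 0L)) {
    stop("merged cluster with zero cells: ",
         paste(names(cl)[lengths(cl) == 0L], collapse = ", "))
  }
  ids <- order_labels(names(cl))
  pairs <- utils::combn(ids, 2L)
  weights <- if (only50) c(even = 0.5) else c(even = 0.5, one = 0.7, two = 0.3)

  with_preserved_rng({
    set.seed(seed)
    profs <- list(); pair_rows <- list(); wclass <- list(); setlab <- list()
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      for (w in names(weights)) {
        wa <- weights[[w]]
        xa <- x$values[, sample(cl[[a]], num_doubs, replace = TRUE), drop = FALSE]
        xb <- x$values[, sample(cl[[b]], num_doubs, replace = TRUE), drop = FALSE]
        mix <- wa * xa + (1 - wa) * xb
        colnames(mix) <- sprintf("syn.%s.%s.%s.%d", a, b, w, seq_len(num_doubs))
        profs[[length(profs) + 1L]] <- mix
        pair_rows[[length(pair_rows) + 1L]] <-
          matrix(rep(c(a, b), each = num_doubs), ncol = 2L)
        wclass[[length(wclass) + 1L]] <- rep(w, num_doubs)
        setlab[[length(setlab) + 1L]] <- rep(sprintf("%s|%s.%s", a, b, w), num_doubs)
      }
    }
    structure(list(
      profiles = do.call(cbind, profs),
      pair = do.call(rbind, pair_rows),
      weight_class = factor(unlist(wclass), levels = c("even", "one", "two")),
      set = unlist(setlab),
      seed = seed
    ), class = "synthetic_doublets")
  })
}

#' @exportS3Method base::print
print.synthetic_doublets <- function(x, ...) {
  cat(sprintf("synthetic_doublets: %d profiles over %d sets (seed %d)\n",
              ncol(x$profiles), length(unique(x$set)), x$seed))
  invisible(x)
}

# evaluate expr with the caller's RNG state restored afterwards
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
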