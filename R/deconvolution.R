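#' Simplex-constrained deconvolution of one expression profile
#'
#' Estimates the fractional contribution of each reference signature to a
#' profile by solving the equality-constrained non-negative least-squares
#' problem `argmin ||S x - y||^2  s.t.  x >= 0, sum(x) = 1` with an
#' active-set method. The result is the deconvolution cell profile (DCP):
#' a length-n vector of non-negative weights summing to 1. Weights in
#' `(-1e-9, 0)` left by the solver are clipped to zero and the vector
#' renormalized.
#'
#' @param profile Numeric vector (one expression column over the marker
#'   genes). Must not be all zero.
#' @param signature_matrix Genes x n reference matrix, n >= 2. Rank
#'   deficiency on the marker genes triggers a warning; a solution is still
#'   returned.
#' @param scale_mode `"none"` (default) fits in the provided value space;
#'   `"zscore"` standardizes each signature column and the profile first.
#' @return Named length-n DCP vector (names = reference column names).
#' @export
solve_dcp <- function(profile, signature_matrix, scale_mode = c("none", "zscore")) {
  scale_mode <- match.arg(scale_mode)
  S <- as.matrix(signature_matrix)
  y <- as.numeric(profile)
  if (length(y) != nrow(S)) stop("profile length must equal the signature gene axis")
  if (ncol(S) < 2L) stop("signature matrix needs at least 2 columns")
  if (all(y == 0)) stop("all-zero profile: no deconvolution possible")
  if (qr(S)$rank < ncol(S)) {
    warning("signature matrix is rank deficient on the marker genes; ",
            "DCP weights may not be unique")
  }
  if (scale_mode == "zscore") {
    S <- apply(S, 2L, zscore)
    y <- zscore(y)
  }
  x <- lsei_nnls(S, y)
  x[x > -1e-9 & x < 0] <- 0
  if (any(x < 0)) stop("solver returned weights below tolerance")  # not expected
  x <- x / sum(x)
  stats::setNames(x, colnames(S))
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

# active-set solver for min ||Sx - y||^2 s.t. sum(x) = 1, x >= 0
lsei_nnls <- function(S, y, tol = 1e-10, max_iter = 100L) {
  n <- ncol(S)
  G <- crossprod(S)            # n x n
  h <- crossprod(S, y)         # n x 1
  solve_eq <- function(P) {
    k <- length(P)
    KKT <- rbind(cbind(2 * G[P, P, drop = FALSE], 1), c(rep(1, k), 0))
    rhs <- c(2 * h[P], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) {
      ridge <- diag(c(rep(1e-10 * max(1, sum(diag(G))), k), 0))
      solve(KKT + ridge, rhs)
    })
    sol
  }
  passive <- seq_len(n)
  x <- numeric(n)
  for (iter in seq_len(max_iter)) {
    sol <- solve_eq(passive)
    xp <- sol[seq_along(passive)]
    # inner loop: drop negative components until the equality solution is feasible
    while (any(xp < -tol) && length(passive) > 1L) {
      passive <- passive[-which.min(xp)]
      sol <- solve_eq(passive)
      xp <- sol[seq_along(passive)]
    }
    x <- numeric(n)
    x[passive] <- pmax(xp, 0)
    lambda <- sol[length(sol)]
    active <- setdiff(seq_len(n), passive)
    if (!length(active)) break
    # dual feasibility: gradient of the active components must not pull inward
    g <- 2 * (G %*% x - h)
    mu <- g[active] + lambda
    if (min(mu) >= -1e-9 * max(1, abs(lambda))) break
    passive <- sort(c(passive, active[which.min(mu)]))
  }
  x
}

#' Deconvolution cell profiles for a set of expression columns
#'
#' Runs [solve_dcp()] on every column of a profile matrix against the merged
#' reference signatures and returns one DCP row per profile.
#'
#' @param profiles Genes x p numeric matrix (cells or synthetic profiles), an
#'   [annotated_expression()], or a `synthetic_doublets` object.
#' @param signatures Genes x n reference signature matrix (e.g. the
#'   `signatures` element of [merge_clusters()]).
#' @param scale_mode Passed to [solve_dcp()].
#' @return p x n matrix of DCP weights; rows named by profile, columns by
#'   reference.
#' @export
dcp_table <- function(profiles, signatures, scale_mode = "none") {
  if (inherits(profiles, "annotated_expression")) profiles <- profiles$values
  if (inherits(profiles, "synthetic_doublets")) profiles <- profiles$profiles
  profiles <- as.matrix(profiles)
  missing <- setdiff(rownames(signatures), rownames(profiles))
  extra <- setdiff(rownames(profiles), rownames(signatures))
  if (length(missing) || length(extra)) {
    stop("gene axis mismatch between profiles and signatures",
         if (length(missing)) paste0("; missing from profiles: ",
                                     paste(missing, collapse = ", ")) else "",
         if (length(extra)) paste0("; absent from signatures: ",
                                   paste(extra, collapse = ", ")) else "")
  }
  profiles <- profiles[rownames(signatures), , drop = FALSE]
  out <- t(apply(profiles, 2L, solve_dcp, signature_matrix = signatures,
                 scale_mode = scale_mode))
  dimnames(out) <- list(colnames(profiles), colnames(signatures))
  out
}

#' Mean DCP of each synthetic doublet set
#'
#' @param dcps DCP matrix from [dcp_table()] over synthetic profiles.
#' @param sets Per-profile set labels (the `set` element of
#'   [generate_synthetics()]).
#' @return Sets x n matrix of arithmetic-mean DCPs, rows named by set label.
#' @export
synthetic_mean_dcps <- function(dcps, sets) {
  stopifnot(nrow(dcps) == length(sets))
  sums <- rowsum(dcps, group = sets, reorder = FALSE)
  sums / as.vector(table(factor(sets, levels = rownames(sums))))
}
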