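# Independent oracles and small fixture builders used across the suite.

# annotated expression with explicit everything
make_ae <- function(values, cell_cluster, gene_cluster = NULL) {
  annotated_expression(values, cell_cluster, gene_cluster)
}

# 3 genes x 4 cells, two clusters of two cells
tiny_ae <- function() {
  v <- matrix(c(1, 0, 2,
                1.5, 0, 2.5,
                0, 3, 1,
                0, 3.5, 0.5), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("c1", "c2", "c3", "c4")))
  make_ae(v, c(1, 1, 2, 2))
}

# brute-force simplex grid search for min ||Sx - y||^2, x >= 0, sum x = 1
grid_dcp <- function(S, y, step = 1e-3) {
  n <- ncol(S)
  obj <- function(X) colSums((S %*% X - as.vector(y))^2)
  if (n == 2L) {
    x1 <- seq(0, 1, by = step)
    X <- rbind(x1, 1 - x1)
  } else if (n == 3L) {
    g <- seq(0, 1, by = step)
    grid <- expand.grid(x1 = g, x2 = g)
    grid <- grid[grid$x1 + grid$x2 <= 1 + 1e-12, ]
    X <- rbind(grid$x1, grid$x2, pmax(1 - grid$x1 - grid$x2, 0))
  } else {
    stop("grid oracle supports 2 or 3 references")
  }
  o <- obj(X)
  i <- which.min(o)
  list(x = X[, i], objective = o[i])
}

dcp_objective <- function(S, y, x) sum((S %*% x - as.vector(y))^2)

# independently coded Markov clustering: plain loops, Frobenius convergence,
# cluster read-off via union-find over attractor supports
reference_mcl <- function(B, expansion = 2, inflation = 2, max_iter = 200,
                          tol = 1e-8) {
  n <- nrow(B)
  M <- B
  diag(M) <- 1
  for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
  for (it in 1:max_iter) {
    E <- M
    for (k in seq_len(expansion - 1)) E <- E %*% M
    Iom <- E^inflation
    for (j in 1:n) Iom[, j] <- Iom[, j] / sum(Iom[, j])
    if (sqrt(sum((Iom - M)^2)) < tol) { M <- Iom; break }
    M <- Iom
  }
  parent <- 1:n
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:n) {
    if (M[i, i] > 1e-5) {
      members <- which(M[i, ] > 1e-5)
      for (m in members) parent[find(m)] <- find(i)
    }
  }
  vapply(1:n, find, integer(1))
}

canon_partition <- function(p) match(p, unique(p))

expect_same_partition <- function(a, b) {
  expect_identical(canon_partition(a), canon_partition(unname(b)))
}

# adjacency matrix of complete blocks given a membership vector
block_adjacency <- function(membership) {
  outer(membership, membership, "==") * 1
}

# direct per-gene one-way ANOVA + Tukey oracle via aov()/TukeyHSD()
aov_oracle <- function(values, groups, focus) {
  groups <- factor(groups)
  others <- setdiff(levels(groups), focus)
  res <- lapply(seq_len(nrow(values)), function(i) {
    d <- data.frame(y = values[i, ], g = groups)
    fit <- stats::aov(y ~ g, data = d)
    s <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    pair_names <- rownames(tk)
    tkp <- vapply(others, function(o) {
      j <- which(pair_names %in% c(paste0(focus, "-", o), paste0(o, "-", focus)))
      tk[j, "p adj"]
    }, numeric(1))
    c(F = s$`F value`[1], p = s$`Pr(>F)`[1], tkp)
  })
  out <- do.call(rbind, res)
  list(F = out[, "F"], p = out[, "p"],
       tukey = out[, others, drop = FALSE])
}

# fixture-scale pipeline evaluation helper
fixture_eval <- function(sim, only50 = FALSE, seed = 7, min_uniq = 4,
                         n_runs = 1) {
  res <- run_pipeline(run_config(sim$marker, only50 = only50, seed = seed,
                                 min_uniq = min_uniq, n_runs = n_runs))
  called <- res$bundle$final_doublets_groups$cell
  truth_doub <- sim$truth$cell[grepl("doublet", sim$truth$type)]
  list(result = res, called = called, truth_doublets = truth_doub,
       perf = confusion(called, truth_doub, sim$truth$cell))
}
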