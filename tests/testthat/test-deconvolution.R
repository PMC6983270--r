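test_that("disjoint-support and exact-column profiles recover exact weights", {
  S <- diag(2)
  dimnames(S) <- list(c("g1", "g2"), c("r1", "r2"))
  expect_equal(unname(solve_dcp(c(0.3, 0.7), S)), c(0.3, 0.7))

  set.seed(12)
  S3 <- matrix(runif(15, 0.1, 3), 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("r", 1:3)))
  for (j in 1:3) {
    x <- solve_dcp(S3[, j], S3)
    ej <- as.numeric(seq_len(3) == j)
    expect_equal(unname(x), ej, tolerance = 1e-6)
  }
})

test_that("the active-set solution matches the simplex grid oracle and quadprog", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(2:3, 1)
    S <- matrix(runif(5 * n, 0, 2), 5, n,
                dimnames = list(paste0("g", 1:5), paste0("r", 1:n)))
    y <- runif(5, 0, 2)
    x <- solve_dcp(y, S)
    expect_true(all(x >= 0))
    expect_equal(sum(x), 1, tolerance = 1e-6)
    g <- grid_dcp(S, y, step = 1e-3)
    expect_lte(dcp_objective(S, y, x), g$objective + 1e-5)

    qp <- quadprog::solve.QP(
      Dmat = 2 * crossprod(S) + diag(1e-10, n),
      dvec = 2 * crossprod(S, y),
      Amat = cbind(rep(1, n), diag(n)),
      bvec = c(1, rep(0, n)), meq = 1)
    expect_equal(dcp_objective(S, y, x),
                 dcp_objective(S, y, qp$solution), tolerance = 1e-6)
  }
})

test_that("rescaled profiles are solved to optimality on their own scale", {
  # the simplex constraint ties the fit to the profile's scale, so a scaled
  # profile defines a different (still exactly solved) problem
  set.seed(5)
  S <- matrix(runif(12, 0, 2), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("r", 1:3)))
  y <- runif(4, 0.1, 2)
  for (c in c(0.5, 1, 7.3)) {
    x <- solve_dcp(c * y, S)
    g <- grid_dcp(S, c * y, step = 1e-3)
    expect_lte(dcp_objective(S, c * y, x), g$objective + 1e-5)
    expect_equal(sum(x), 1, tolerance = 1e-6)
  }
})

test_that("degenerate deconvolution inputs error or warn as specified", {
  S <- diag(2); dimnames(S) <- list(c("g1", "g2"), c("r1", "r2"))
  expect_error(solve_dcp(c(0, 0), S), "all-zero")
  Sdef <- cbind(r1 = c(1, 2), r2 = c(2, 4))
  rownames(Sdef) <- c("g1", "g2")
  expect_warning(solve_dcp(c(1, 2), Sdef), "rank deficient")
  P <- matrix(1, 2, 1, dimnames = list(c("g1", "gX"), "p"))
  expect_error(dcp_table(P, S), "gX")
})

test_that("reference self-deconvolution is the identity and mixtures recover weights", {
  set.seed(18)
  sim <- simulate_dataset(simulation_params(
    n_clusters = 2, cells_per_cluster = 80, n_marker_genes_per_cluster = 25,
    n_background_genes = 0, doublet_rate = 0, seed = 18))
  md <- merge_clusters(sim$marker)
  sig <- md$signatures
  self <- dcp_table(sig, sig)
  expect_equal(unname(self), diag(2), tolerance = 1e-6)

  # even mixtures of orthogonal, equal-norm references average near 0.5/0.5
  Sorth <- rbind(cbind(rep(2, 10), rep(0, 10)), cbind(rep(0, 10), rep(2, 10)))
  dimnames(Sorth) <- list(paste0("g", 1:20), c("r1", "r2"))
  vo <- pmax(Sorth[, c(rep(1, 30), rep(2, 30))] +
               matrix(rnorm(20 * 60, 0, 0.2), 20), 0)
  colnames(vo) <- paste0("cell", 1:60)
  xo <- make_ae(vo, rep(1:2, each = 30))
  so <- generate_synthetics(xo, num_doubs = 500, only50 = TRUE, seed = 44)
  sig_o <- compute_signatures(xo, "centroid")
  mean_dcp <- synthetic_mean_dcps(dcp_table(so, sig_o), so$set)
  expect_equal(unname(mean_dcp[1, ]), c(0.5, 0.5), tolerance = 0.02)
})

test_that("70/30 mixed profiles peak near a 0.3/0.7 deconvolution split", {
  # two-reference fixture mimicking a species-mixing design
  sim <- simulate_dataset(simulation_params(
    n_clusters = 2, cells_per_cluster = 150, n_marker_genes_per_cluster = 30,
    n_background_genes = 0, doublet_rate = 0.2, prob_even = 0,
    mix_space = "log", seed = 27))
  md <- merge_clusters(sim$marker)
  dcps <- dcp_table(sim$marker, md$signatures)
  doub <- sim$truth$cell[sim$truth$type == "heterotypic_doublet"]
  w <- dcps[doub, 1]
  major <- pmax(w, 1 - w)
  # distribution sits in the 30/70 region, not at an even split
  expect_gt(mean(major), 0.62)
  expect_lt(mean(major), 0.85)
  expect_gt(mean(major > 0.6), 0.8)
})
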