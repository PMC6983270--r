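test_that("signatures are per-gene means or medians over cluster cells", {
  v <- matrix(c(1, 1,  3, 2,  10, 10), nrow = 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  x <- make_ae(v, c(1, 1, 1))
  sig_c <- compute_signatures(x, "centroid")
  sig_m <- compute_signatures(x, "medoid")
  expect_equal(unname(sig_c[, 1]), c(mean(c(1, 3, 10)), mean(c(1, 2, 10))))
  expect_equal(unname(sig_m[, 1]), c(3, 2))

  # a one-cell cluster's signature is that cell in both modes
  y <- make_ae(v, c(1, 2, 3))
  expect_equal(compute_signatures(y, "centroid"), v, ignore_attr = TRUE)
  expect_equal(compute_signatures(y, "medoid"), v, ignore_attr = TRUE)

  # [1, 3] -> centroid 2, medoid 2; [1, 2, 10] -> centroid 13/3, medoid 2
  z <- make_ae(matrix(c(1, 3), 1, 2, dimnames = list("g", c("a", "b"))), c(1, 1))
  expect_equal(unname(compute_signatures(z, "centroid")[1, 1]), 2)
  expect_equal(unname(compute_signatures(z, "medoid")[1, 1]), 2)
  expect_equal(unname(sig_c["gB", 1]), 13 / 3)
})

test_that("markov clustering recovers blocks, merges complete graphs, splits bridged triangles", {
  B2 <- block_adjacency(c(1, 1, 2, 2, 2))
  expect_same_partition(mcl(B2), c(1, 1, 2, 2, 2))

  expect_same_partition(mcl(matrix(1, 4, 4)), rep(1, 4))

  tri <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))) {
    tri[e[1], e[2]] <- tri[e[2], e[1]] <- 1
  }
  got <- mcl(tri, inflation = 2)
  expect_same_partition(got, c(1, 1, 1, 2, 2, 2))
  expect_same_partition(got, reference_mcl(tri))

  expect_error(mcl(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(mcl(tri, max_iter = 1), "converge")
})

test_that("markov clustering equals connected components on random complete-block graphs", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    membership <- sort(sample(k, sample(4:12, 1), replace = TRUE))
    B <- block_adjacency(membership)
    expect_same_partition(mcl(B), canon_partition(membership))
  }
})

test_that("the merge threshold binds high-correlation pairs and respects rho'", {
  set.seed(14)
  # three clusters: 1 and 2 share a marker program, 3 is distinct
  base <- c(rep(5, 10), rep(0.2, 10))
  sig_src <- cbind(base + rnorm(20, 0, 0.2),
                   base + rnorm(20, 0, 0.2),
                   c(rep(0.2, 10), rep(5, 10)) + rnorm(20, 0, 0.2))
  v <- sig_src[, c(1, 1, 2, 2, 3, 3)] + matrix(rnorm(120, 0, 0.05), 20)
  v <- pmax(v, 0)
  dimnames(v) <- list(paste0("g", 1:20), paste0("c", 1:6))
  x <- make_ae(v, rep(1:3, each = 2))

  md <- merge_clusters(x, rho_prime = 1)
  # oracle: recompute the threshold from the correlation matrix directly
  sig <- compute_signatures(x, "centroid")
  r <- cor(sig)
  off <- r[upper.tri(r)]
  expect_equal(md$rho_T, mean(off) + sd(off), tolerance = 1e-12)
  expect_identical(unname(md$B[1, 2]), as.numeric(r[1, 2] >= md$rho_T))
  expect_same_partition(md$partition, c(1, 1, 2))
  expect_identical(ncol(md$signatures), 2L)
  # merged signature equals the centroid of the pooled member cells
  expect_equal(unname(md$signatures[, 1]), unname(rowMeans(v[, 1:4])))

  # a huge rho' keeps the identity partition
  md10 <- merge_clusters(x, rho_prime = 10)
  expect_same_partition(md10$partition, 1:3)

  # identical signatures: sd 0, rho_T 1, everything merges
  vid <- v[, c(1, 1, 1, 1, 1, 1)] + 0
  colnames(vid) <- paste0("c", 1:6)
  mid <- merge_clusters(make_ae(vid, rep(1:3, each = 2)), rho_prime = 1)
  expect_identical(ncol(mid$signatures), 1L)
})

test_that("merged-cluster count is monotone non-increasing as rho' decreases", {
  sim <- simulate_dataset(simulation_params(
    n_clusters = 4, cells_per_cluster = 30, n_marker_genes_per_cluster = 15,
    n_background_genes = 0, doublet_rate = 0, seed = 2))
  tab <- sweep_rho_prime(sim$marker, rho_grid = seq(1.5, 0.5, by = -0.25))
  expect_true(all(diff(tab$n_merged) <= 0))
  # and the number of binding pairs never drops as the threshold loosens
  ones <- vapply(seq(1.5, 0.5, by = -0.25), function(rp)
    sum(merge_clusters(sim$marker, rp)$B), numeric(1))
  expect_true(all(diff(ones) >= 0))
})

test_that("two-cluster inputs only merge when signatures coincide", {
  v <- matrix(c(5, 0.2, 5.2, 0.3, 0.2, 5, 0.4, 5.1), nrow = 2,
              dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
  x <- make_ae(v, c(1, 1, 2, 2))
  md <- merge_clusters(x, rho_prime = 0.5)
  expect_same_partition(md$partition, c(1, 2))

  vid <- v[, c(1, 2, 1, 2)] + 0
  colnames(vid) <- paste0("c", 1:4)
  mid <- merge_clusters(make_ae(vid, c(1, 1, 2, 2)), rho_prime = 1)
  expect_same_partition(mid$partition, c(1, 1))
})

test_that("zero-variance signature columns warn and correlate as zero", {
  # cluster 1 centroid is (2, 2): constant across genes, correlation undefined
  vv <- matrix(c(2, 2, 2, 2,
                 2, 2, 5, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
  expect_warning(md <- merge_clusters(make_ae(vv, c(1, 1, 2, 2)), rho_prime = 1),
                 "zero-variance")
  expect_identical(unname(md$r[1, 2]), 0)
})
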