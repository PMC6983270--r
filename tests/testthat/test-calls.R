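test_that("remove step assigns singlets and putative doublets by nearest DCP", {
  refs <- rbind(`1` = c(0.95, 0.05), `2` = c(0.05, 0.95))
  syn <- rbind(`1|2.even` = c(0.5, 0.5))
  cells <- rbind(a = c(0.95, 0.05), b = c(0.5, 0.5))
  oc <- c(a = "1", b = "1")
  calls <- remove_step(cells, refs, syn, oc)
  expect_identical(unname(calls$state), c("singlet", "putative_doublet"))
  expect_identical(calls$table$best_match, c("1", "1|2.even"))
  # hand-checked Euclidean distances for cell b: 0.636, 0.636, 0
  expect_equal(calls$table$similarity[2], 0)
  d_ref <- sqrt(sum((c(0.5, 0.5) - c(0.95, 0.05))^2))
  expect_equal(d_ref, 0.6363961, tolerance = 1e-6)

  # an exact tie resolves toward the singlet interpretation
  tie <- rbind(t = c(0.5, 0.5))
  calls_tie <- remove_step(tie, rbind(`1` = c(0.5, 0.5), `2` = c(0, 1)), syn,
                           c(t = "1"))
  expect_identical(unname(calls_tie$state), "singlet")
})

test_that("remove step switches to Pearson above two references", {
  refs <- rbind(`1` = c(0.90, 0.05, 0.05),
                `2` = c(0.05, 0.90, 0.05),
                `3` = c(0.05, 0.05, 0.90))
  syn <- rbind(`1|2.even` = c(0.46, 0.46, 0.08))
  cells <- rbind(a = c(0.88, 0.07, 0.05), b = c(0.44, 0.49, 0.07))
  calls <- remove_step(cells, refs, syn, c(a = "1", b = "1"))
  expect_identical(unname(calls$state), c("singlet", "putative_doublet"))
  # similarity is the Pearson correlation of DCP vectors
  expect_equal(calls$table$similarity[1],
               cor(c(0.88, 0.07, 0.05), c(0.90, 0.05, 0.05)))

  const <- rbind(z = c(1, 1, 1) / 3)
  expect_warning(remove_step(const, refs, syn, c(z = "1")), "constant DCP")
})

test_that("recluster labels come from the top two contributors plus weight suffix", {
  refs <- rbind(`1` = c(1, 0, 0), `2` = c(0, 1, 0), `3` = c(0, 0, 1))
  syn <- rbind(`1|3.two` = c(0.3, 0.05, 0.65), `2|3.even` = c(0.1, 0.55, 0.35))
  cells <- rbind(a = c(0.1, 0.6, 0.3), b = c(0.32, 0.05, 0.63),
                 c = c(0.1, 0.6, 0.3))
  colnames(cells) <- colnames(refs) <- colnames(syn) <- c("1", "2", "3")
  calls <- remove_step(cells, refs, syn, c(a = "2", b = "1", c = "2"))
  calls <- recluster_step(calls, cells, only50 = FALSE)
  expect_identical(unname(calls$recluster_label[c("a", "c")]),
                   rep("2|3.even", 2))          # identical DCPs share a label
  expect_identical(unname(calls$recluster_label["b"]), "1|3.two")

  # without the 30/70 option the suffix is dropped
  calls50 <- remove_step(cells, refs, rbind(`2|3.even` = c(0.1, 0.55, 0.35)),
                         c(a = "2", b = "1", c = "2"))
  calls50 <- recluster_step(calls50, cells, only50 = TRUE)
  expect_identical(unname(calls50$recluster_label["a"]), "2|3")

  # single non-zero component: next largest (zero) with lowest-id tie-break
  one <- rbind(o = c(0, 1, 0))
  colnames(one) <- c("1", "2", "3")
  co <- remove_step(one, refs, syn, c(o = "2"))
  co$table$is_putative_doublet <- TRUE  # force through recluster
  co <- recluster_step(co, one, only50 = TRUE)
  expect_identical(unname(co$recluster_label["o"]), "1|2")
})

test_that("aggregate ANOVA equals the direct aov/TukeyHSD computation", {
  set.seed(71)
  n_genes <- 200
  groups <- rep(c("Z", "A", "B", "C"), times = c(8, 12, 10, 9))
  X <- matrix(rnorm(n_genes * length(groups)), n_genes,
              dimnames = list(paste0("g", 1:n_genes), NULL))
  X[1:5, groups == "Z"] <- X[1:5, groups == "Z"] + 3  # a few real signals

  got <- chunked_anova(X, groups, focus = "Z", chunk_size = 37)
  oracle <- aov_oracle(X, groups, focus = "Z")
  expect_equal(got$F, unname(oracle$F), tolerance = 1e-8)
  expect_equal(got$p, unname(oracle$p), tolerance = 1e-8)
  expect_equal(unname(got$tukey[, colnames(oracle$tukey)]),
               unname(oracle$tukey), tolerance = 1e-8)

  # chunk boundaries do not change anything
  whole <- chunked_anova(X, groups, focus = "Z", chunk_size = 100000)
  expect_identical(got$F, whole$F)
  expect_identical(got$tukey, whole$tukey)
})

test_that("aggregate ANOVA edge cases: F = t^2, flat genes, zero df", {
  set.seed(72)
  g2 <- rep(c("Z", "A"), each = 10)
  X <- matrix(rnorm(50 * 20), 50)
  got <- chunked_anova(X, g2, focus = "Z")
  tstat <- apply(X, 1, function(v) t.test(v[g2 == "Z"], v[g2 == "A"],
                                          var.equal = TRUE)$statistic)
  expect_equal(got$F, unname(tstat^2), tolerance = 1e-8)

  flat <- matrix(5, 3, 20)
  gotf <- chunked_anova(flat, g2, focus = "Z")
  expect_equal(gotf$F, rep(0, 3))
  expect_equal(gotf$p, rep(1, 3))

  expect_warning(chunked_anova(matrix(rnorm(4), 2), c("Z", "A"), focus = "Z"),
                 "degrees of freedom")
})

test_that("unique genes require significance against and excess over every cluster", {
  set.seed(80)
  nz <- 10; nc <- 10
  cells <- c(sprintf("z%d", 1:nz), sprintf("a%d", 1:nc), sprintf("b%d", 1:nc),
             sprintf("c%d", 1:nc))
  ref_groups <- list(A = sprintf("a%d", 1:nc), B = sprintf("b%d", 1:nc),
                     C = sprintf("c%d", 1:nc))
  X <- matrix(rnorm(4 * 40, 0, 0.1), 4, 40,
              dimnames = list(c("unique", "flat", "partial", "noise"), cells))
  X["unique", 1:nz] <- rnorm(nz, 5, 0.1)
  X["flat", ] <- 2
  X["partial", 1:nz] <- rnorm(nz, 2, 0.1)            # higher than A, B ...
  X["partial", 31:40] <- rnorm(nc, 4, 0.1)           # ... but lower than C
  ug <- unique_genes(X, sprintf("z%d", 1:nz), ref_groups)
  expect_identical(ug, "unique")

  # oracle agreement for the engineered gene
  oracle <- aov_oracle(X["unique", , drop = FALSE],
                       c(rep(".Z", nz), rep(c("A", "B", "C"), each = nc)), ".Z")
  expect_lt(oracle$p[1], 1e-10)
  expect_true(all(oracle$tukey[1, ] < 1e-6))
})

test_that("rescue is all-or-none per cluster, thresholded and monotone in U", {
  sim <- simulate_dataset(simulation_params(
    n_clusters = 2, cells_per_cluster = 100, n_marker_genes_per_cluster = 25,
    n_background_genes = 0, doublet_rate = 0.05, transitional = TRUE,
    transitional_cells = 20, n_unique_genes = 10, seed = 31))
  x <- standardize_labels(sim$marker)$expression
  md <- merge_clusters(x)
  dcps <- dcp_table(md$merged_expression, md$signatures)
  syn <- generate_synthetics(md$merged_expression, seed = 31)
  syn_mean <- synthetic_mean_dcps(dcp_table(syn, md$signatures), syn$set)
  refs <- dcp_table(md$signatures, md$signatures)
  calls <- remove_step(dcps, refs, syn_mean, md$merged_expression$cell_cluster)
  calls <- recluster_step(calls, dcps)

  r4 <- rescue_step(calls, md$merged_expression, U = 4)
  trans_cells <- sim$truth$cell[sim$truth$type == "transitional"]
  expect_true(all(r4$calls$state[trans_cells] == "rescued_singlet"))
  trans_row <- r4$report[r4$report$decision == "rescued", ]
  expect_true(all(trans_row$unique_gene_count >= 4))

  # U = 0 rescues every doublet cluster; singlets are never relabelled
  r0 <- rescue_step(calls, md$merged_expression, U = 0)
  expect_false(any(r0$calls$state == "final_doublet"))
  sing <- names(calls$state)[calls$state == "singlet"]
  expect_true(all(r0$calls$state[sing] == "singlet"))
  expect_true(all(r4$calls$state[sing] == "singlet"))

  # every putative doublet ends in exactly one terminal state
  put <- names(calls$state)[calls$state == "putative_doublet"]
  expect_true(all(r4$calls$state[put] %in% c("rescued_singlet", "final_doublet")))

  # the final-doublet set can only grow as U increases
  sets <- lapply(c(0, 4, 100), function(u) {
    rs <- rescue_step(calls, md$merged_expression, U = u)
    names(rs$calls$state)[rs$calls$state == "final_doublet"]
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))

  expect_error(rescue_step(calls, md$merged_expression, U = -1), "U must")
})
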