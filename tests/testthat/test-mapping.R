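toy_matrix <- function() {
  m <- matrix(c(1, 2, 3,
                3, 2, 1,
                2, 2, 2,
                4, 0, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("cell", 1:3)))
  m
}

test_that("model vectors are per-cluster means over the gene list", {
  m <- toy_matrix()
  labels <- tibble::tibble(cell_id = colnames(m),
                           cluster = c("k1", "k1", "k2"))
  mv <- build_model_vectors(m, labels)
  expect_equal(unname(mv$vectors[, "k1"]), c(1.5, 2.5, 2, 2))
  expect_equal(unname(mv$vectors[, "k2"]), m[, 3], ignore_attr = TRUE)

  # two identical cells average to either one (idempotent mean)
  m2 <- m
  m2[, 2] <- m2[, 1]
  mv2 <- build_model_vectors(m2, labels)
  expect_equal(unname(mv2$vectors[, "k1"]), unname(m2[, 1]))

  expect_error(build_model_vectors(m, labels, genes = c("g1", "gX")),
               "absent")
  expect_error(build_model_vectors(m, labels[1:2, ]), "without a cluster")
})

test_that("cells map to their most correlated model vector", {
  pair <- gen_expression_pair(n_genes = 100, n_marker_per_cluster = 10,
                              noise_sd = 0, cells_per_cluster = 3, seed = 2)
  mv <- build_model_vectors(pair$postnatal$expr, pair$postnatal$labels)

  # a cell equal to a model vector correlates at exactly 1 with it
  probe <- mv$vectors[, "P2", drop = FALSE]
  colnames(probe) <- "probe"
  res <- map_cells(probe, mv)
  expect_equal(res$best_cluster, "P2")
  expect_equal(res$best_r, 1)

  # a mean-reflected cell anti-correlates at exactly -1
  anti <- 2 * mean(mv$vectors[, "P2"]) - mv$vectors[, "P2", drop = FALSE]
  colnames(anti) <- "anti"
  r <- attr(map_cells(anti, mv), "r_matrix")
  expect_equal(unname(r[1, "P2"]), -1)

  # zero-variance cells are flagged, gene mismatches error
  flat <- matrix(1, nrow = 100, ncol = 1,
                 dimnames = list(rownames(mv$vectors), "flat"))
  expect_true(map_cells(flat, mv)$zero_variance)
  bad <- probe
  rownames(bad)[1] <- "not_a_gene"
  expect_error(map_cells(bad, mv), "lacks")
})

test_that("Pearson assignment is invariant to per-cell affine rescaling", {
  pair <- gen_expression_pair(n_genes = 100, cells_per_cluster = 5, seed = 3)
  mv <- build_model_vectors(pair$postnatal$expr, pair$postnatal$labels)
  expr <- pair$embryonic$expr
  rescaled <- sweep(sweep(expr, 2, runif(ncol(expr), 0.5, 3), "*"),
                    2, runif(ncol(expr), -1, 1), "+")
  r1 <- map_cells(expr, mv)
  r2 <- map_cells(rescaled, mv)
  expect_equal(r1$best_cluster, r2$best_cluster)
  expect_equal(r1$best_r, r2$best_r, tolerance = 1e-12)
})

test_that("empirical p-values count strictly larger permuted maxima", {
  pair <- gen_expression_pair(n_genes = 100, n_marker_per_cluster = 10,
                              effect = 3, noise_sd = 0.3,
                              cells_per_cluster = 4, seed = 4)
  mv <- build_model_vectors(pair$postnatal$expr, pair$postnatal$labels)
  res <- empirical_pvalues(pair$embryonic$expr, mv, n_perm = 50, seed = 5)
  # strong marker structure survives gene shuffling essentially never
  expect_lt(mean(res$p_emp), 0.05)
  expect_true(all(res$p_emp >= 0 & res$p_emp <= 1))
  expect_error(empirical_pvalues(pair$embryonic$expr, mv, n_perm = 0),
               "n_perm")
})

test_that("the BH gate matches the step-up oracle and its forced cases", {
  expect_equal(fdr_gate(c(0.01, 0.02, 0.04, 0.8))$fdr,
               c(0.04, 0.04, 16 / 300, 0.8))
  expect_equal(fdr_gate(c(0.01, 0.02, 0.04, 0.8))$mapped,
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdr_gate(rep(0, 5))$mapped))
  expect_false(any(fdr_gate(rep(1, 5))$mapped))

  for (seed in 1:20) {
    p <- withr::with_seed(seed, runif(sample.int(20, 1)))
    expect_equal(fdr_gate(p)$fdr, oracle_bh(p))
  }
})

test_that("mapping fractions sum to one over mapped cells", {
  res <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:12),
    best_cluster = c(rep("P1", 8), rep("P2", 2), "P1", "P2"),
    mapped = c(rep(TRUE, 10), FALSE, FALSE)
  )
  labels <- tibble::tibble(cell_id = res$cell_id,
                           cluster = c(rep("E1", 10), "E2", "E2"))
  fr <- mapping_fractions(res, labels)
  e1 <- fr[fr$embryonic_cluster == "E1", ]
  expect_equal(e1$fraction[e1$postnatal_cluster == "P1"], 0.8)
  expect_equal(sum(e1$fraction), 1)
  # E2 has no mapped cells: flagged, NA fractions
  expect_true("E2" %in% attr(fr, "no_mapped_cells"))
  expect_true(is.na(fr$fraction[fr$embryonic_cluster == "E2"]))
})

test_that("Spearman cluster distances match direct rank correlations", {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1,
                1, 3, 2, 4), ncol = 4,
              dimnames = list(paste0("g", 1:4), paste0("cell", 1:4)))
  labels <- setNames(paste0("k", 1:4), colnames(m))
  d <- cluster_distance_spearman(m, labels)
  expect_equal(d["k1", "k2"], 0)      # monotone transform, rho = 1
  expect_equal(d["k1", "k3"], 2)      # reversed ranks, rho = -1
  expect_equal(d["k1", "k4"],
               1 - cor(m[, 1], m[, 4], method = "spearman"))
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), rep(0, 4))

  mc <- m
  mc[, 2] <- 5
  dc <- cluster_distance_spearman(mc, labels)
  expect_equal(attr(dc, "constant"), "k2")
  expect_true(is.na(dc["k1", "k2"]))
})

test_that("the end-to-end mapping wrapper gates by FDR", {
  pair <- gen_expression_pair(n_genes = 150, cells_per_cluster = 8, seed = 6)
  mv <- build_model_vectors(pair$postnatal$expr, pair$postnatal$labels)
  res <- map_embryonic_cells(pair$embryonic$expr, mv, n_perm = 40, seed = 7)
  expect_s3_class(res, "mapping_result")
  expect_true(all(res$fdr[res$mapped] < 0.1))
  truth <- unname(pair$cluster_map[pair$embryonic$labels$cluster])
  expect_gt(mean(res$best_cluster == truth), 0.95)
  g <- glance(res)
  expect_equal(g$n_cells, nrow(res))
  expect_s3_class(tidy(res), "tbl_df")
})
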