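test_that("pair metric follows the shared-clone definition", {
  # clone A: 2 cells in s1, 1 in s2 (n=3, k=3, p=1);
  # clone B: 1 s1, 1 s2, 2 s3 (n=4, k=2, p=0.5) -> metric 1.5
  ct <- make_clone_table(c(3, 4))
  ann <- make_annotation(ct, c("s1", "s1", "s2", "s1", "s2", "s3", "s3"))
  expect_equal(pair_metric(ct, ann, "s1", "s2"), 1.5)

  # one 2-cell clone split across the pair -> k = n = 2, metric 1
  ct2 <- make_clone_table(2)
  ann2 <- make_annotation(ct2, c("s1", "s2"))
  expect_equal(pair_metric(ct2, ann2, "s1", "s2"), 1)

  # no clone spanning both states -> empty sum
  ct3 <- dplyr::bind_rows(ct2, tibble::tibble(cell_id = "x1",
                                              clone_id = "c99",
                                              dataset_id = "D1"))
  ann4 <- make_annotation(ct3, c("s1", "s1", "s2"))
  expect_equal(pair_metric(ct3, ann4, "s1", "s2"), 0)

  expect_error(pair_metric(ct, ann, "s1", "nope"), "unknown state")
  expect_error(pair_metric(ct, ann, "s1", "s1"), "distinct")
})

test_that("pair metric is symmetric, bounded and matches the literal oracle", {
  for (seed in 1:25) {
    inst <- random_instance(n_clones = sample(3:10, 1), max_size = 5,
                            states = c("A", "B", "C"), seed = seed)
    m_ab <- pair_metric(inst$clone_table, inst$annotation, "A", "B")
    expect_equal(m_ab, pair_metric(inst$clone_table, inst$annotation, "B", "A"))
    expect_equal(m_ab, oracle_pair_metric(inst$clone_table, inst$annotation,
                                          "A", "B"))
    spanning <- inst$annotation |>
      dplyr::inner_join(inst$clone_table, by = "cell_id") |>
      dplyr::summarise(span = all(c("A", "B") %in% state), .by = clone_id)
    expect_gte(m_ab, 0)
    expect_lte(m_ab, sum(spanning$span))
  }
})

test_that("singleton-only tables yield degenerate flagged nulls", {
  ct <- make_clone_table(rep(1, 10))
  ann <- make_annotation(ct, rep(c("A", "B"), 5))
  res <- coupling_zscores(ct, ann, n_perm = 50, seed = 1)
  expect_equal(res$observed["A", "B"], 0)
  expect_equal(res$z["A", "B"], 0)
  expect_true(res$degenerate["A", "B"])
})

test_that("Monte-Carlo z agrees with the exhaustive-permutation oracle", {
  # 8 cells, clones {3,3,2}, states 4xA 4xB: 70 distinct arrangements
  ct <- make_clone_table(c(3, 3, 2))
  ann <- make_annotation(ct, c("A", "A", "B", "B", "B", "A", "A", "B"))
  exact <- oracle_exact_null(ct, ann, "A", "B")
  obs <- pair_metric(ct, ann, "A", "B")
  z_exact <- (obs - exact$mean) / exact$sd

  n_perm <- 10000
  res <- coupling_zscores(ct, ann, n_perm = n_perm, seed = 7)
  se_z <- sqrt((1 + z_exact^2 / 2) / n_perm)
  expect_lt(abs(res$z["A", "B"] - z_exact), 3 * se_z)
  expect_equal(res$observed["A", "B"], obs)
})

test_that("identical seeds reproduce the coupling result exactly", {
  inst <- random_instance(30, 6, c("A", "B", "C", "D"), seed = 3)
  r1 <- coupling_zscores(inst$clone_table, inst$annotation, n_perm = 300,
                         seed = 11)
  r2 <- coupling_zscores(inst$clone_table, inst$annotation, n_perm = 300,
                         seed = 11)
  expect_identical(r1, r2)
  expect_error(coupling_zscores(inst$clone_table, inst$annotation,
                                n_perm = 1), "n_perm")
})

test_that("coupling correlations exclude the pair's own coordinates", {
  states <- c("A", "B", "C", "D", "E")
  z <- matrix(0, 5, 5, dimnames = list(states, states))
  z[upper.tri(z)] <- c(1.2, -0.5, 0.8, 2.0, 0.3, -1.0, 0.7, 1.5, -0.2, 0.9)
  z <- z + t(z)
  diag(z) <- NA
  fake <- structure(
    list(states = states, z = z,
         degenerate = matrix(FALSE, 5, 5)),
    class = "coupling_result"
  )
  corr <- coupling_correlations(fake)
  # oracle: plain Pearson on the shared coordinates
  idx <- c(3, 4, 5)
  expect_equal(corr["A", "B"], cor(z["A", idx], z["B", idx]))
  idx2 <- c(1, 2, 5)
  expect_equal(corr["C", "D"], cor(z["C", idx2], z["D", idx2]))
  expect_true(isSymmetric(corr))

  # identical rows correlate at 1, mirrored rows at -1
  z2 <- z
  z2["B", ] <- z2["A", ]
  z2[, "B"] <- z2[, "A"]
  z2["B", "A"] <- z2["A", "B"] <- 0
  fake2 <- structure(list(states = states, z = z2,
                          degenerate = matrix(FALSE, 5, 5)),
                     class = "coupling_result")
  corr2 <- coupling_correlations(fake2)
  expect_equal(corr2["A", "B"], 1)
})

test_that("null-calibrated z and planted-signal detection behave sanely", {
  # small single-replicate versions of the calibration checks
  set.seed(5)
  ct <- make_clone_table(rep(4, 40))
  ann <- make_annotation(ct, sample(LETTERS[1:4], 160, replace = TRUE))
  res <- coupling_zscores(ct, ann, n_perm = 2000, seed = 6)
  zs <- res$z[upper.tri(res$z)]
  expect_lt(abs(mean(zs)), 0.75)  # loose single-replicate bound

  # plant strong A-B coupling
  planted_states <- c(rep(c("A", "B"), 40),
                      sample(LETTERS[3:6], 80, replace = TRUE))
  ann2 <- make_annotation(ct, planted_states[seq_len(nrow(ct))])
  res2 <- coupling_zscores(ct, ann2, n_perm = 2000, seed = 7)
  off <- res2$z[upper.tri(res2$z)]
  off <- off[off != res2$z["A", "B"]]
  expect_gt(res2$z["A", "B"], max(off))
})

test_that("lineage dendrogram clusters correlation rows", {
  states <- c("A", "B", "C", "D")
  corr <- diag(4)
  dimnames(corr) <- list(states, states)
  corr["A", "B"] <- corr["B", "A"] <- 0.9
  corr["C", "D"] <- corr["D", "C"] <- 0.9
  corr["A", "C"] <- corr["C", "A"] <- -0.8
  corr["A", "D"] <- corr["D", "A"] <- -0.8
  corr["B", "C"] <- corr["C", "B"] <- -0.8
  corr["B", "D"] <- corr["D", "B"] <- -0.8
  out <- lineage_dendrogram(corr, k = 2)
  g <- setNames(out$groups$group, out$groups$state)
  expect_equal(g[["A"]], g[["B"]])
  expect_equal(g[["C"]], g[["D"]])
  expect_false(g[["A"]] == g[["C"]])
  expect_equal(length(out$tree$order), 4L)

  dup <- corr
  dup["B", ] <- dup["A", ]
  dup[, "B"] <- dup[, "A"]
  dup["A", "B"] <- dup["B", "A"] <- 1
  tree <- lineage_dendrogram(dup)$tree
  expect_equal(min(tree$height), 0)

  expect_error(lineage_dendrogram(corr[1, 1, drop = FALSE]), "2 states")
})

test_that("clone composition categories follow the 100%/80% thresholds", {
  ct <- make_clone_table(c(3, 6, 8, 2))
  classes <- c(rep("astrocyte", 3),                 # clone 1: 100%, glia
               rep("neuron", 5), "astrocyte",       # clone 2: 5/6 > 0.8, mixed
               rep("neuron", 4), rep("astrocyte", 4), # clone 3: 0.5, mixed
               rep("vascular", 2))                  # clone 4: other
  ann <- make_annotation(ct, state = classes, classes = classes)
  comp <- clone_composition(ct, ann)
  comp <- comp[order(comp$clone_id), ]
  expect_equal(comp$purity_category, c("100%", ">80%", "<80%", "100%"))
  expect_equal(comp$lineage_category,
               c("glia_only", "mixed", "mixed", "other"))
  expect_equal(comp$dominant_fraction[2], 5 / 6)

  fr <- composition_fractions(comp)
  lineage <- fr[fr$categorisation == "lineage" & fr$category != "other", ]
  expect_equal(sum(lineage$fraction), 1)  # denominators exclude 'other'

  ann_bad <- ann
  ann_bad$class[1] <- NA
  expect_error(clone_composition(ct, ann_bad), "class")
})

test_that("clone intersections tally state sets with conservation", {
  ct <- make_clone_table(c(2, 2, 2, 1))
  ann <- make_annotation(ct, c("s1", "s2", "s1", "s2", "s1", "s3", "s1"))
  out <- clone_intersections(ct, ann, c("s1", "s2", "s3"))
  expect_equal(out$intersections$n_clones[
    out$intersections$state_set == "s1&s2"], 2L)
  expect_equal(out$intersections$n_clones[
    out$intersections$state_set == "s1&s3"], 1L)
  # the singleton clone occupies one state only -> excluded as non-dispersing
  expect_equal(sum(out$intersections$n_clones), 3L)
  expect_equal(out$set_sizes$n_cells[out$set_sizes$state == "s1"], 4L)

  all_in <- clone_intersections(ct, ann, c("s1", "s2", "s3"),
                                dispersing_only = FALSE)
  expect_equal(sum(all_in$intersections$n_clones), 4L)
  expect_error(clone_intersections(ct, ann, character(0)), "empty")
})
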