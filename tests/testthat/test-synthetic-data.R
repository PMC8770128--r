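test_that("combinatorial diversity is the product of pool sizes", {
  expect_identical(combinatorial_diversity(c(500, 500, 500)), 125e6)
  expect_identical(combinatorial_diversity(c(1, 1, 1)), 1)
  lib <- gen_barcode_library(pool_sizes = c(6, 5, 4), seed = 1)
  expect_identical(combinatorial_diversity(lib), 120)
})

test_that("library pools are distinct, Hamming-separated and seeded", {
  lib <- gen_barcode_library(pool_sizes = c(25, 25), seed = 7)
  for (pool in lib$pools) {
    expect_false(anyDuplicated(pool) > 0)
    expect_true(all(nchar(pool) == lib$fragment_length))
    d <- vapply(seq_along(pool), function(i) {
      if (i == length(pool)) return(5L)
      min(vapply(pool[(i + 1):length(pool)],
                 function(s) sum(charToRaw(s) != charToRaw(pool[i])),
                 integer(1)))
    }, integer(1))
    expect_true(all(d >= 5))
  }

  lib2 <- gen_barcode_library(pool_sizes = c(4, 4), seed = 7)
  lib3 <- gen_barcode_library(pool_sizes = c(4, 4), seed = 7)
  expect_identical(lib2, lib3)
  lib4 <- gen_barcode_library(pool_sizes = c(4, 4), seed = 8)
  expect_false(identical(lib2$pools, lib4$pools))
})

test_that("infeasible Hamming separation fails explicitly", {
  expect_error(
    gen_barcode_library(pool_sizes = 10, fragment_length = 3,
                        min_pool_hamming = 5, seed = 1),
    "separat"
  )
  expect_error(
    gen_barcode_library(pool_sizes = 300, fragment_length = 4,
                        min_pool_hamming = 4, seed = 1),
    "infeasible"
  )
})

test_that("clonal population honours sizes, states and modes", {
  lib <- gen_barcode_library(pool_sizes = c(10, 10, 10), seed = 1)
  pop <- gen_clonal_population(10, dist_constant(3), states = "A",
                               library = lib, seed = 2)
  expect_equal(nrow(pop$cells), 30)
  expect_equal(dplyr::n_distinct(pop$cells$clone_id), 10)
  expect_true(all(table(pop$cells$clone_id) == 3))
  expect_true(all(pop$cells$state == "A"))

  popT <- gen_clonal_population(8, dist_constant(4), states = c("A", "B"),
                                mode = "TrackerSeq",
                                integrations_per_cell = dist_constant(2),
                                seed = 3)
  expect_true(all(lengths(popT$clone_barcodes$integrations) == 2))
  expect_true(all(nchar(unlist(popT$clone_barcodes$integrations)) == 37))

  expect_error(gen_clonal_population(0, states = "A", library = lib), "at least 1")
  expect_error(gen_clonal_population(3, states = character(0), library = lib),
               "state")
})

test_that("two-state clones are multi-state at the designed rate", {
  # constant clone size 4, two equiprobable states:
  # P(clone spans both states) = 1 - 2 * (1/2)^4 = 0.875
  lib <- gen_barcode_library(pool_sizes = c(10, 10, 10), seed = 1)
  n_clones <- 300
  pop <- gen_clonal_population(n_clones, dist_constant(4),
                               states = c("A", "B"), library = lib,
                               seed = 11)
  multi <- pop$cells |>
    dplyr::summarise(multi = dplyr::n_distinct(state) > 1,
                     .by = clone_id)
  p <- 0.875
  half_width <- qnorm(0.995) * sqrt(p * (1 - p) / n_clones)
  expect_gt(mean(multi$multi), p - half_width)
  expect_lt(mean(multi$multi), p + half_width)
})

test_that("clone-size distribution matches its declared mean", {
  sizes <- withr::with_seed(5, draw_dist(dist_truncgeom(mean = 3, max = 30),
                                         500))
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 3), 3 * se + 0.15)  # small truncation bias
  expect_true(all(sizes >= 1 & sizes <= 30))
})

test_that("reads reflect UMI, PCR and error settings", {
  lib <- gen_barcode_library(pool_sizes = c(10, 10, 10), seed = 1)
  pop <- gen_clonal_population(6, dist_constant(2), states = "A",
                               library = lib, seed = 2)

  clean <- gen_reads(pop, lib, umi_per_molecule = dist_constant(12),
                     pcr_dups = dist_constant(5), seed = 3)
  per_cell <- dplyr::count(clean, cell_barcode)
  expect_true(all(per_cell$n == 12))  # every cell clears the 9-UMI threshold
  expect_equal(sum(clean$read_count), 5 * nrow(clean))

  # forced UMI errors: every molecule sheds a 1-mismatch satellite read;
  # Hamming-1 collapse recovers the zero-error molecule count
  noisy <- gen_reads(pop, lib, umi_per_molecule = dist_constant(12),
                     pcr_dups = dist_constant(5), umi_error_rate = 1,
                     seed = 4)
  triples <- tibble::tibble(cell_id = noisy$cell_barcode, umi = noisy$umi,
                            barcode_id = noisy$payload,
                            read_count = noisy$read_count)
  collapsed <- dedup_umis(triples, mismatch = 1)
  expect_true(all(collapsed$umi_count == 12))

  # determinism and mode mismatch
  expect_identical(gen_reads(pop, lib, seed = 9), gen_reads(pop, lib, seed = 9))
  other <- gen_barcode_library(pool_sizes = c(10, 10, 10), seed = 99)
  expect_error(gen_reads(pop, other, seed = 1), "viral ind")
})

test_that("expression pair has the designed marker structure", {
  pair0 <- gen_expression_pair(n_genes = 120, n_marker_per_cluster = 10,
                               noise_sd = 0, cells_per_cluster = 4, seed = 1)
  mv <- build_model_vectors(pair0$postnatal$expr, pair0$postnatal$labels)
  assigned <- map_cells(pair0$embryonic$expr, mv)
  truth <- pair0$cluster_map[pair0$embryonic$labels$cluster]
  expect_true(all(assigned$best_cluster == unname(truth)))

  expect_identical(gen_expression_pair(n_genes = 120, seed = 3,
                                       cells_per_cluster = 3),
                   gen_expression_pair(n_genes = 120, seed = 3,
                                       cells_per_cluster = 3))
  expect_error(gen_expression_pair(n_genes = 50, n_marker_per_cluster = 20),
               "marker")
  expect_true(all(pair0$embryonic$expr >= 0))
})
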