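layout14 <- sticr_layout(fragment_length = 14, n_fragments = 3,
                         index_length = 6)

test_that("fragment extraction cuts at fixed offsets and rejects short reads", {
  f1 <- strrep("A", 14); f2 <- strrep("C", 14); f3 <- strrep("G", 14)
  ix <- "TTTTTT"
  reads <- tibble::tibble(payload = c(
    paste0(f1, f2, f3, ix),
    paste0(f1, f2, f3, ix, "ACGTACGT"),   # flanks beyond the span
    substr(paste0(f1, f2, f3, ix), 1, 38)  # truncated
  ))
  out <- extract_fragments(reads, layout14)
  expect_equal(out$extract_status, c("ok", "ok", "truncated"))
  expect_equal(out$frag1[1:2], c(f1, f1))
  expect_equal(out$frag2[1:2], c(f2, f2))
  expect_equal(out$frag3[1:2], c(f3, f3))
  expect_equal(out$viral_index[1:2], c(ix, ix))
  expect_true(is.na(out$frag1[3]))
})

test_that("fragment alignment resolves unique hits within 2 mismatches", {
  pool <- c(F1 = "AAAAAAAAAA", F2 = "CCCCCCCCCC", F3 = "AAAAAAGGGG")
  # distance 0, distance <= 2 unique, distance 3 from everything
  hits <- align_fragment(c("AAAAAAAAAA", "AAAAAAAATA", "CCCTTTCCCC"), pool)
  expect_equal(hits$status, c("matched", "matched", "none"))
  expect_equal(hits$fragment_id[1:2], c("F1", "F1"))
  expect_equal(hits$distance[1:2], c(0L, 1L))

  # equidistant (2 mismatches) from F1 and F3 -> ambiguous
  amb <- align_fragment("AAAAAAAAGG", pool)
  expect_equal(amb$status, "ambiguous")
  expect_true(is.na(amb$fragment_id))

  expect_error(align_fragment("AAAA", pool), "length")
})

test_that("directional UMI collapse merges error satellites", {
  # exact duplicates collapse by grouping
  t1 <- tibble::tibble(cell_id = "c", umi = c("AAAA", "AAAA"),
                       barcode_id = "B", read_count = 1L)
  expect_equal(dedup_umis(t1)$umi_count, 1L)

  # a 1-mismatch low-count satellite merges into its parent
  t2 <- tibble::tibble(cell_id = "c", umi = c("AAAA", "AAAT"),
                       barcode_id = "B", read_count = c(10L, 1L))
  expect_equal(dedup_umis(t2)$umi_count, 1L)

  # two Hamming-1 star clusters -> 2 surviving UMIs; the connected-merge
  # count on this 6-UMI set is the oracle
  stars <- tibble::tibble(
    cell_id = "c",
    umi = c("AAAAA", "AAAAT", "AAATA", "GGGGG", "GGGGC", "GGGCG"),
    barcode_id = "B",
    read_count = c(10L, 1L, 1L, 8L, 1L, 1L)
  )
  expect_equal(dedup_umis(stars)$umi_count, 2L)

  # zero-mismatch mode counts distinct UMIs; empty input is empty output
  expect_equal(dedup_umis(t2, mismatch = 0)$umi_count, 2L)
  expect_equal(nrow(dedup_umis(t2[0, ])), 0L)
})

test_that("tier decision table matches the candidacy/dominance/final rules", {
  p <- sticr_params()
  cases <- list(
    list(counts = c(B1 = 10), tier = 1L, winner = "B1"),
    list(counts = c(B1 = 25, B2 = 5), tier = 2L, winner = "B1"),
    list(counts = c(B1 = 8), tier = NA, winner = NA),        # fails final >= 9
    list(counts = c(B1 = 20, B2 = 6), tier = NA, winner = NA), # 20 < 5 x 6
    list(counts = c(B1 = 20, B2 = 4), tier = 1L, winner = "B1"), # lone candidate
    list(counts = c(B1 = 45, B2 = 9), tier = 2L, winner = "B1"),
    list(counts = c(B1 = 4, B2 = 3), tier = NA, winner = NA)  # no candidate
  )
  for (case in cases) {
    counts <- tibble::tibble(cell_id = "cell", barcode_id = names(case$counts),
                             umi_count = as.integer(case$counts))
    call <- assign_clonal_barcode(counts, p)
    if (is.na(case$tier)) {
      expect_equal(nrow(call), 0L)
    } else {
      expect_equal(call$tier, case$tier)
      expect_equal(call$barcode_id, case$winner)
    }
  }
})

test_that("clone table groups by barcode within dataset and blacklists across", {
  calls <- tibble::tibble(
    cell_id = sprintf("c%d", 1:6),
    barcode_id = c("X", "X", "X", "Y", "Y", "Z"),
    umi_count = 10L,
    tier = c(1L, 1L, 1L, 1L, 1L, 2L),
    dataset_id = c("A", "A", "A", "A", "B", "A")
  )
  ct <- build_clone_table(calls, tier_policy = "tier1_only")
  # X forms one clone of 3; Y seen in A and B -> blacklisted; Z is tier 2
  expect_equal(sort(attr(ct, "blacklist")), "Y")
  expect_equal(nrow(ct), 3L)
  expect_equal(dplyr::n_distinct(ct$clone_id), 1L)

  ct2 <- build_clone_table(calls, tier_policy = "tier1_and_2")
  expect_equal(nrow(ct2), 4L)

  dup <- dplyr::bind_rows(calls,
                          tibble::tibble(cell_id = "c1", barcode_id = "Q",
                                         umi_count = 10L, tier = 1L,
                                         dataset_id = "A"))
  expect_error(build_clone_table(dup), "more than one barcode")
})

test_that("clone size summary separates multicellular and singleton clones", {
  ct <- make_clone_table(c(3, 3, 3))
  s <- clone_size_summary(ct)
  expect_equal(s$mean_size, 3)
  expect_equal(s$sem_size, 0)
  expect_equal(s$max_size, 3)

  ct2 <- make_clone_table(c(2, 4))
  s2 <- clone_size_summary(ct2)
  expect_equal(s2$mean_size, 3)
  expect_equal(s2$sem_size, 1)  # sd(c(2,4))/sqrt(2) = sqrt(2)/sqrt(2)
  expect_equal(s2$max_size, 4)

  ct3 <- make_clone_table(c(1, 1, 1))
  s3 <- clone_size_summary(ct3)
  expect_equal(s3$n_multicellular, 0L)
  expect_equal(s3$n_singleton, 3L)
})

test_that("raising the final UMI threshold never adds cells", {
  counts <- withr::with_seed(42, tibble::tibble(
    cell_id = rep(sprintf("c%02d", 1:40), each = 2),
    barcode_id = rep(c("B1", "B2"), 40),
    umi_count = sample.int(30, 80, replace = TRUE)
  ))
  retained <- vapply(5:20, function(thr) {
    nrow(assign_clonal_barcode(counts, sticr_params(min_umi_final = thr)))
  }, integer(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("noiseless synthetic reads recover the planted clones exactly", {
  lib <- gen_barcode_library(pool_sizes = c(30, 30, 30), seed = 21)
  pop <- gen_clonal_population(25, dist_truncgeom(3, 10),
                               states = c("A", "B"), library = lib, seed = 22)
  reads <- gen_reads(pop, lib, umi_per_molecule = dist_constant(12),
                     pcr_dups = dist_constant(2), seed = 23)
  res <- call_sticr_clones(reads, fragment_reference(lib))
  expect_equal(nrow(res$clone_table), nrow(pop$cells))
  truth <- pop$cells$clone_id[match(res$clone_table$cell_id,
                                    pop$cells$cell_id)]
  expect_equal(ari(truth, res$clone_table$clone_id), 1)
})
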