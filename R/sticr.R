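#' Parameters for STICR barcode processing
#'
#' Thresholds controlling combinatorial-barcode clone calling, with the
#' defaults used throughout: fragments align with up to 2 mismatches, UMIs
#' collapse at 1 mismatch, a barcode needs at least 5 distinct UMIs to be a
#' candidate clonal barcode, a dominant barcode needs at least 5 times the
#' UMI count of the runner-up, and any call used for clonal analysis needs at
#' least 9 distinct UMIs.
#'
#' @param max_fragment_mismatch maximum Hamming mismatches per fragment.
#' @param umi_collapse_mismatch UMI collapse radius (Hamming).
#' @param min_umi_candidate minimum distinct UMIs for barcode candidacy.
#' @param dominance_factor fold-dominance required for a tier-2 call.
#' @param min_umi_final minimum distinct UMIs for a retained call.
#' @return A list of class `sticr_params`.
#' @export
sticr_params <- function(max_fragment_mismatch = 2L,
                         umi_collapse_mismatch = 1L,
                         min_umi_candidate = 5L,
                         dominance_factor = 5,
                         min_umi_final = 9L) {
  p <- list(max_fragment_mismatch = as.integer(max_fragment_mismatch),
            umi_collapse_mismatch = as.integer(umi_collapse_mismatch),
            min_umi_candidate = as.integer(min_umi_candidate),
            dominance_factor = dominance_factor,
            min_umi_final = as.integer(min_umi_final))
  if (any(unlist(p) < 0)) abort("sticr_params must be non-negative")
  if (p$min_umi_final < p$min_umi_candidate) {
    abort("min_umi_final must be >= min_umi_candidate")
  }
  structure(p, class = "sticr_params")
}

#' Read layout of a combinatorial barcode payload
#'
#' Describes where the barcode fragments and the viral index sit within the
#' payload sequence: `n_fragments` fragments of `fragment_length` nt
#' concatenated from `offset`, followed by the `index_length`-nt viral index.
#' Flanking sequence outside the declared span is ignored.
#'
#' @param fragment_length fragment length (nt).
#' @param n_fragments number of fragments.
#' @param index_length viral-index length (nt).
#' @param offset 1-based position of the first fragment in the payload.
#' @return A list of class `sticr_layout`.
#' @export
sticr_layout <- function(fragment_length = 14L, n_fragments = 3L,
                         index_length = 6L, offset = 1L) {
  stopifnot(fragment_length >= 1L, n_fragments >= 1L, index_length >= 0L,
            offset >= 1L)
  structure(
    list(fragment_length = as.integer(fragment_length),
         n_fragments = as.integer(n_fragments),
         index_length = as.integer(index_length),
         offset = as.integer(offset)),
    class = "sticr_layout"
  )
}

layout_span <- function(layout) {
  layout$offset - 1L +
    layout$n_fragments * layout$fragment_length + layout$index_length
}

#' Build a fragment reference from pools or a synthetic library
#'
#' @param pools list of named character vectors (fragment id -> sequence),
#'   one per pool, or a `barcode_library`.
#' @param viral_indices known viral-index sequences (exact match required
#'   downstream).
#' @return A list of class `fragment_reference`.
#' @export
fragment_reference <- function(pools, viral_indices = character()) {
  if (inherits(pools, "barcode_library")) {
    lib <- pools
    if (length(viral_indices) == 0L) viral_indices <- lib$viral_index
    pools <- lib$pools
  }
  for (pool in pools) {
    if (is.null(names(pool)) || anyDuplicated(names(pool))) {
      abort("each pool must have unique fragment-id names")
    }
    if (anyDuplicated(unname(pool))) abort("pool sequences must be distinct")
    if (length(unique(nchar(pool))) != 1L) {
      abort("all sequences within a pool must have equal length")
    }
  }
  structure(list(pools = pools, viral_indices = viral_indices),
            class = "fragment_reference")
}

#' Extract barcode fragments and viral index from payload sequences
#'
#' Cuts each payload at the fixed offsets of `layout` into its fragment and
#' index substrings. Payloads shorter than the layout span are rejected with
#' reason `"truncated"`; flanking sequence beyond the span is ignored.
#'
#' @param reads tibble with at least a `payload` column (e.g. from
#'   [gen_reads()] or [read_reads()]).
#' @param layout an [sticr_layout()]; taken from `attr(reads, "layout")` when
#'   `NULL`.
#' @return The input tibble with added columns `frag1`..`fragN`,
#'   `viral_index` and `extract_status` (`"ok"` or `"truncated"`; fragment
#'   columns are `NA` for rejected reads).
#' @export
extract_fragments <- function(reads, layout = NULL) {
  assert_columns(reads, "payload")
  layout <- layout %||% attr(reads, "layout")
  if (!inherits(layout, "sticr_layout")) {
    abort("an sticr_layout is required (pass `layout` or use STICR reads)")
  }
  span <- layout_span(layout)
  ok <- nchar(reads$payload) >= span

  out <- as_tibble(reads)
  starts <- layout$offset + (seq_len(layout$n_fragments) - 1L) *
    layout$fragment_length
  for (i in seq_len(layout$n_fragments)) {
    col <- paste0("frag", i)
    out[[col]] <- ifelse(
      ok,
      substr(reads$payload, starts[i], starts[i] + layout$fragment_length - 1L),
      NA_character_
    )
  }
  idx_start <- layout$offset + layout$n_fragments * layout$fragment_length
  out$viral_index <- ifelse(
    ok, substr(reads$payload, idx_start, idx_start + layout$index_length - 1L),
    NA_character_
  )
  out$extract_status <- ifelse(ok, "ok", "truncated")
  out
}

#' Align fragment sequences to a reference pool with mismatch tolerance
#'
#' Exhaustive Hamming scan against one fragment pool: a query matches the
#' unique pool entry within `max_mismatch` substitutions; queries with no
#' entry in range return status `"none"`, and queries where two or more
#' entries tie at the minimum qualifying distance return `"ambiguous"` (such
#' reads are discarded downstream). Query length must equal the pool's
#' sequence length — a length mismatch is an error, not a non-match.
#'
#' @param seqs character vector of fragment sequences (NAs pass through with
#'   status `"none"`).
#' @param pool named character vector (fragment id -> sequence).
#' @param max_mismatch maximum Hamming distance for a match.
#' @return A tibble with columns `seq`, `fragment_id` (NA unless matched),
#'   `distance` and `status` (`"matched"`, `"none"`, `"ambiguous"`).
#' @export
align_fragment <- function(seqs, pool, max_mismatch = 2L) {
  if (is.null(names(pool))) abort("pool must be a named character vector")
  pool_len <- unique(nchar(pool))
  if (length(pool_len) != 1L) abort("pool sequences must have equal length")
  live <- !is.na(seqs)
  if (any(nchar(seqs[live]) != pool_len)) {
    abort(sprintf("query length differs from pool sequence length (%d)",
                  pool_len))
  }

  uq <- unique(seqs[live])
  # exact matches first; only the rest need the Hamming scan
  exact <- match(uq, pool)
  fid <- names(pool)[exact]
  dist <- ifelse(is.na(exact), NA_integer_, 0L)
  status <- ifelse(is.na(exact), NA_character_, "matched")

  for (i in which(is.na(exact))) {
    d <- hamming_to_pool(uq[i], pool)
    dmin <- min(d)
    if (dmin > max_mismatch) {
      status[i] <- "none"
    } else if (sum(d == dmin) > 1L) {
      status[i] <- "ambiguous"
      dist[i] <- dmin
    } else {
      status[i] <- "matched"
      fid[i] <- names(pool)[which.min(d)]
      dist[i] <- dmin
    }
  }

  pos <- match(seqs, uq)
  tibble(
    seq = seqs,
    fragment_id = fid[pos],
    distance = dist[pos],
    status = ifelse(is.na(seqs), "none", status[pos])
  )
}

#' Deduplicate UMIs with directional single-mismatch collapse
#'
#' Collapses PCR/sequencing UMI errors within each (cell, barcode) group:
#' UMIs are visited in order of decreasing read support (ties broken
#' lexicographically) and a UMI merges into the first already-surviving UMI
#' within `mismatch` Hamming distance; otherwise it survives. The returned
#' count is the number of surviving UMIs — never more than the distinct input
#' UMIs. `mismatch = 0` reduces to counting distinct UMIs.
#'
#' @param triples tibble with columns `cell_id`, `umi`, `barcode_id` and
#'   optionally `read_count` (default 1); duplicate rows are summed.
#' @param mismatch Hamming collapse radius (UMIs must share a length within
#'   each group).
#' @return A tibble of `cell_id`, `barcode_id`, `umi_count` (surviving UMIs).
#' @export
dedup_umis <- function(triples, mismatch = 1L) {
  assert_columns(triples, c("cell_id", "umi", "barcode_id"))
  if (nrow(triples) == 0L) {
    return(tibble(cell_id = character(), barcode_id = character(),
                  umi_count = integer()))
  }
  if (!"read_count" %in% names(triples)) triples$read_count <- 1L

  counts <- triples |>
    dplyr::group_by(.data$cell_id, .data$barcode_id, .data$umi) |>
    dplyr::summarise(reads = sum(.data$read_count), .groups = "drop")

  counts |>
    dplyr::group_by(.data$cell_id, .data$barcode_id) |>
    dplyr::summarise(
      umi_count = collapse_umi_count(.data$umi, .data$reads, mismatch),
      .groups = "drop"
    )
}

# number of surviving UMIs under sequential directional collapse
collapse_umi_count <- function(umis, reads, mismatch) {
  if (mismatch == 0L || length(umis) == 1L) return(length(umis))
  if (length(unique(nchar(umis))) != 1L) {
    abort("UMIs within a cell must have equal length")
  }
  ord <- order(-reads, umis)
  umis <- umis[ord]
  surviving <- umis[1L]
  for (u in umis[-1L]) {
    if (all(hamming_to_pool(u, surviving) > mismatch)) {
      surviving <- c(surviving, u)
    }
  }
  length(surviving)
}

#' Assign each cell its clonal barcode by tiered dominance
#'
#' Applies the tiered dominant-barcode rule per cell. Barcodes with at least
#' `min_umi_candidate` distinct UMIs are candidates. A cell with exactly one
#' candidate gets a tier-1 call. A cell with two or more candidates gets a
#' tier-2 call for its most abundant barcode only if that barcode has at
#' least `dominance_factor` times the UMI count of the next most abundant
#' one. Either way the call is kept only if its UMI count reaches
#' `min_umi_final`; cells failing any rule yield no call.
#'
#' @param cell_counts tibble of `cell_id`, `barcode_id`, `umi_count` (one row
#'   per cell-barcode pair, e.g. from [dedup_umis()]); an optional
#'   `dataset_id` column is carried through.
#' @param params an [sticr_params()].
#' @return A tibble of calls: `cell_id`, `barcode_id`, `umi_count`, `tier`
#'   (1 or 2), plus `dataset_id` if present. Cells without a qualifying call
#'   are absent.
#' @export
assign_clonal_barcode <- function(cell_counts, params = sticr_params()) {
  assert_columns(cell_counts, c("cell_id", "barcode_id", "umi_count"))
  stopifnot(inherits(params, "sticr_params"))
  if (any(cell_counts$umi_count <= 0)) abort("umi_count must be positive")

  keys <- c("cell_id", intersect("dataset_id", names(cell_counts)))
  cell_counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(dplyr::desc(.data$umi_count), .data$barcode_id,
                   .by_group = TRUE) |>
    dplyr::summarise(
      call = list(call_one_cell(.data$barcode_id, .data$umi_count, params)),
      .groups = "drop"
    ) |>
    tidyr::unnest("call")
}

# tier decision for one cell; barcodes arrive sorted by count desc, id asc
call_one_cell <- function(barcode_id, umi_count, params) {
  none <- tibble(barcode_id = character(), umi_count = integer(),
                 tier = integer())
  cand <- umi_count >= params$min_umi_candidate
  n_cand <- sum(cand)
  if (n_cand == 0L) return(none)
  if (n_cand == 1L) {
    winner <- which(cand)
    tier <- 1L
  } else {
    # candidates occupy the top of the sorted list, so the runner-up to the
    # top candidate is simply the second entry
    if (umi_count[1L] < params$dominance_factor * umi_count[2L]) return(none)
    winner <- 1L
    tier <- 2L
  }
  if (umi_count[winner] < params$min_umi_final) return(none)
  tibble(barcode_id = barcode_id[winner],
         umi_count = as.integer(umi_count[winner]), tier = tier)
}

#' Build a clone table from clonal barcode calls
#'
#' Cells sharing a clonal barcode within a dataset form one clone. Barcodes
#' observed in two or more datasets cannot be trusted as clonal marks (a
#' library collision or contamination) and are blacklisted: all their cells
#' are dropped. Tier filtering follows `tier_policy` — clonal analyses use
#' tier-1 calls only unless tier 2 is explicitly admitted.
#'
#' @param calls tibble of calls with columns `cell_id`, `barcode_id`, `tier`
#'   and `dataset_id`.
#' @param tier_policy `"tier1_only"` (default) or `"tier1_and_2"`.
#' @return A clone table: tibble of `cell_id`, `clone_id`, `dataset_id`,
#'   `barcode_id`, with attribute `blacklist` (the cross-dataset barcodes
#'   removed).
#' @export
build_clone_table <- function(calls, tier_policy = c("tier1_only",
                                                     "tier1_and_2")) {
  tier_policy <- match.arg(tier_policy)
  assert_columns(calls, c("cell_id", "barcode_id", "tier", "dataset_id"))

  dup <- calls |>
    dplyr::count(.data$dataset_id, .data$cell_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("cell(s) with more than one barcode call: %s",
                  paste(head(dup$cell_id, 3L), collapse = ", ")))
  }

  kept <- if (tier_policy == "tier1_only") {
    dplyr::filter(calls, .data$tier == 1L)
  } else {
    dplyr::filter(calls, .data$tier %in% c(1L, 2L))
  }

  blacklist <- kept |>
    dplyr::distinct(.data$barcode_id, .data$dataset_id) |>
    dplyr::count(.data$barcode_id) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::pull(.data$barcode_id)

  table <- kept |>
    dplyr::filter(!.data$barcode_id %in% blacklist) |>
    dplyr::mutate(clone_id = paste(.data$dataset_id, .data$barcode_id,
                                   sep = ":")) |>
    dplyr::select("cell_id", "clone_id", "dataset_id", "barcode_id")

  structure(table, blacklist = blacklist)
}

#' Summarise clone sizes per dataset
#'
#' Multicellular clones (size >= 2) are summarised by mean, standard error
#' and maximum size; singleton clones are counted separately.
#'
#' @param clone_table tibble with `clone_id`, `cell_id` and optionally
#'   `dataset_id` columns.
#' @return A tibble per dataset: `n_clones`, `n_multicellular`,
#'   `n_singleton`, `mean_size`, `sem_size`, `max_size` (multicellular sizes;
#'   `NA` where no multicellular clone exists).
#' @export
clone_size_summary <- function(clone_table) {
  assert_columns(clone_table, c("cell_id", "clone_id"))
  if (nrow(clone_table) == 0L) abort("clone table is empty")
  if (!"dataset_id" %in% names(clone_table)) {
    clone_table$dataset_id <- "all"
  }
  clone_table |>
    dplyr::count(.data$dataset_id, .data$clone_id, name = "size") |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      n_multicellular = sum(.data$size >= 2L),
      n_singleton = sum(.data$size == 1L),
      mean_size = mean(.data$size[.data$size >= 2L]),
      sem_size = sd(.data$size[.data$size >= 2L]) /
        sqrt(sum(.data$size >= 2L)),
      max_size = if (any(.data$size >= 2L)) max(.data$size[.data$size >= 2L])
                 else NA_integer_,
      .groups = "drop"
    )
}

#' Run the full STICR clone-calling pipeline on a read table
#'
#' Convenience wrapper chaining [extract_fragments()], [align_fragment()]
#' (per pool, dropping reads with any unmatched or ambiguous fragment or a
#' viral index not exactly matching a known index), [dedup_umis()],
#' [assign_clonal_barcode()] and [build_clone_table()].
#'
#' @param reads read tibble (`cell_barcode`, `umi`, `payload`, `read_count`).
#' @param reference a [fragment_reference()].
#' @param params an [sticr_params()].
#' @param layout an [sticr_layout()] (defaults to the reads' attribute).
#' @param dataset_id dataset label for the resulting calls.
#' @param tier_policy passed to [build_clone_table()].
#' @return A list with `clone_table`, `calls`, and `funnel` (a tibble of
#'   per-stage record counts).
#' @examples
#' lib <- gen_barcode_library(pool_sizes = c(8, 8, 8), seed = 1)
#' pop <- gen_clonal_population(6, dist_constant(3), states = "A",
#'                              library = lib, seed = 2)
#' reads <- gen_reads(pop, lib, seed = 3)
#' res <- call_sticr_clones(reads, fragment_reference(lib))
#' clone_size_summary(res$clone_table)
#' @export
call_sticr_clones <- function(reads, reference, params = sticr_params(),
                              layout = NULL, dataset_id = "D1",
                              tier_policy = "tier1_only") {
  stopifnot(inherits(reference, "fragment_reference"))
  layout <- layout %||% attr(reads, "layout") %||% sticr_layout(
    fragment_length = unique(nchar(reference$pools[[1]])),
    n_fragments = length(reference$pools),
    index_length = nchar(reference$viral_indices[1] %||% "")
  )

  n_in <- nrow(reads)
  ext <- extract_fragments(reads, layout)
  ok <- ext$extract_status == "ok"

  frag_ids <- matrix(NA_character_, nrow = nrow(ext),
                     ncol = layout$n_fragments)
  matched <- ok
  for (i in seq_len(layout$n_fragments)) {
    al <- align_fragment(ext[[paste0("frag", i)]], reference$pools[[i]],
                         params$max_fragment_mismatch)
    frag_ids[, i] <- al$fragment_id
    matched <- matched & al$status == "matched"
  }
  index_ok <- !is.na(ext$viral_index) &
    ext$viral_index %in% reference$viral_indices
  keep <- matched & index_ok

  triples <- tibble(
    cell_id = ext$cell_barcode[keep],
    umi = ext$umi[keep],
    barcode_id = paste(
      apply(frag_ids[keep, , drop = FALSE], 1L, paste, collapse = "-"),
      ext$viral_index[keep], sep = "@"
    ),
    read_count = ext$read_count[keep]
  )

  counts <- dedup_umis(triples, params$umi_collapse_mismatch)
  counts$dataset_id <- dataset_id
  calls <- assign_clonal_barcode(counts, params)
  clone_table <- build_clone_table(calls, tier_policy)

  funnel <- tibble(
    stage = c("reads_in", "reads_extracted", "reads_aligned",
              "cells_with_call", "cells_in_clones"),
    n = c(n_in, sum(ok), sum(keep), nrow(calls), nrow(clone_table))
  )
  list(clone_table = clone_table, calls = calls, funnel = funnel)
}
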