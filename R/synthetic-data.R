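#' Generate a combinatorial fragment-pool barcode library
#'
#' Builds the reference for a lentiviral combinatorial barcode library: a set
#' of fragment pools (by default three pools of 500 distinct 14-nt fragments)
#' from which each clonal barcode is assembled by concatenating one fragment
#' per pool, followed by a short constant viral index identifying the library.
#' Pools are generated so that every pair of fragments within a pool differs
#' at `min_pool_hamming` or more positions, which keeps mismatch-tolerant
#' alignment (up to 2 mismatches) unambiguous.
#'
#' With `abundance_model = "lognormal"`, each fragment receives a log-normal
#' sampling weight (sd `sigma` on the log scale); a combination's abundance is
#' the product of its fragments' weights. This emulates the skewed barcode
#' abundances of a real plasmid library.
#'
#' @param pool_sizes integer vector, number of fragments per pool.
#' @param fragment_length fragment length in nucleotides.
#' @param min_pool_hamming minimum pairwise Hamming distance within a pool.
#' @param abundance_model `"uniform"` or `"lognormal"`.
#' @param sigma log-scale standard deviation for the log-normal model.
#' @param viral_index constant index sequence for this library; a random 6-mer
#'   if `NULL`.
#' @param seed integer RNG seed; identical seeds give identical libraries.
#' @return An object of class `barcode_library`: pools (named fragment
#'   vectors), per-pool abundance weights, fragment length and viral index.
#' @seealso [combinatorial_diversity()], [gen_clonal_population()]
#' @examples
#' lib <- gen_barcode_library(pool_sizes = c(20, 20, 20), seed = 1)
#' combinatorial_diversity(lib)
#' @export
gen_barcode_library <- function(pool_sizes = c(500L, 500L, 500L),
                                fragment_length = 14L,
                                min_pool_hamming = 5L,
                                abundance_model = c("uniform", "lognormal"),
                                sigma = 1,
                                viral_index = NULL,
                                seed = NULL) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(length(pool_sizes) >= 1L, all(pool_sizes >= 1L),
            fragment_length >= 1L, min_pool_hamming >= 0L, sigma >= 0)
  local_seed(seed)

  pools <- lapply(seq_along(pool_sizes), function(i) {
    pool <- gen_separated_pool(pool_sizes[[i]], fragment_length,
                               min_pool_hamming)
    names(pool) <- sprintf("P%d_F%03d", i, seq_along(pool))
    pool
  })
  names(pools) <- paste0("pool", seq_along(pools))

  weights <- lapply(pool_sizes, function(sz) {
    w <- if (abundance_model == "lognormal") exp(rnorm(sz, sd = sigma))
         else rep(1, sz)
    w / sum(w)
  })

  if (is.null(viral_index)) viral_index <- random_dna(1L, 6L)

  structure(
    list(pools = pools,
         pool_weights = weights,
         fragment_length = as.integer(fragment_length),
         min_pool_hamming = as.integer(min_pool_hamming),
         abundance_model = abundance_model,
         sigma = sigma,
         viral_index = viral_index),
    class = "barcode_library"
  )
}

# rejection-sample a pool of `n` distinct fragments with all pairwise Hamming
# distances >= min_d; fails explicitly when the separation is infeasible
gen_separated_pool <- function(n, len, min_d, max_tries = 500L * n + 1000L) {
  if (min_d > len) {
    abort(sprintf(
      "cannot separate fragments by >= %d mismatches at length %d", min_d, len
    ))
  }
  pool <- character(n)
  k <- 0L
  tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        paste0("pool of size %d with pairwise Hamming >= %d is infeasible at ",
               "fragment length %d (gave up after %d attempts)"),
        n, min_d, len, max_tries
      ))
    }
    cand <- random_dna(1L, len)
    if (k == 0L || all(hamming_to_pool(cand, pool[seq_len(k)]) >= min_d)) {
      k <- k + 1L
      pool[k] <- cand
    }
  }
  pool
}

#' Theoretical combinatorial diversity of a barcode library
#'
#' The number of distinct combinatorial barcodes the library can encode: the
#' product of its pool sizes (e.g. three pools of 500 fragments give
#' 500^3 = 125,000,000 combinations).
#'
#' @param x a `barcode_library` or an integer vector of pool sizes.
#' @return A single number (exact in double precision for realistic pools).
#' @examples
#' combinatorial_diversity(c(500, 500, 500))
#' @export
combinatorial_diversity <- function(x) {
  sizes <- if (inherits(x, "barcode_library")) lengths(x$pools) else x
  stopifnot(is.numeric(sizes), length(sizes) >= 1L, all(sizes >= 1))
  prod(as.numeric(sizes))
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf(
    "<barcode_library> %s pools (%s), fragment length %d nt, index %s\n",
    length(x$pools), paste(lengths(x$pools), collapse = " x "),
    x$fragment_length, x$viral_index
  ))
  cat(sprintf("  abundance model: %s; combinatorial diversity: %s\n",
              x$abundance_model,
              format(combinatorial_diversity(x), big.mark = ",")))
  invisible(x)
}

# default transposon barcode mask: 16 random positions (N) bridged by fixed
# trinucleotides, 37 nt total -> 4^16 (~4.3e9) possible barcodes
TRACKER_MASK_DEFAULT <-
  "NNACTNNGACNNTGANNCAGNNATCNNGTANNCGTNN"

#' Generate a clonal cell population with ground-truth lineage labels
#'
#' Simulates a population of barcoded cells organised into clones, the ground
#' truth that clone-calling recovery is scored against. Every cell of a clone
#' carries the clone's lineage mark: in `"STICR"` mode a single combinatorial
#' barcode drawn from `library` according to its abundance weights; in
#' `"TrackerSeq"` mode a fixed set of transposon integration barcodes
#' (distinct 37-nt sequences drawn on the configurable `tracker_mask`).
#' Each cell is additionally assigned a transcriptomic state and a cell class.
#'
#' @param n_clones number of clones.
#' @param clone_size a [dist_constant()]-family spec for cells per clone.
#' @param states character vector of state (cluster) labels.
#' @param state_probs `NULL` (uniform over `states`), a probability vector
#'   over `states` shared by all clones, or an `n_clones x length(states)`
#'   matrix of per-clone state probabilities (cells draw their state
#'   independently from their clone's row).
#' @param mode `"STICR"` or `"TrackerSeq"`.
#' @param library a [gen_barcode_library()] object (required in STICR mode).
#' @param integrations_per_cell count spec for integrations carried by each
#'   clone's cells (TrackerSeq mode; ignored for STICR).
#' @param tracker_mask barcode template; `N` positions are drawn at random,
#'   other positions are fixed. Recorded in the output metadata.
#' @param classes named character vector mapping each state to a cell class
#'   (e.g. `c(S1 = "neuron", S2 = "astrocyte")`); defaults to `"neuron"` for
#'   every state.
#' @param dataset_id dataset label attached to every cell.
#' @param cell_barcode_length length of the droplet cell barcodes used as
#'   cell ids.
#' @param seed integer RNG seed.
#' @return An object of class `sim_population` with elements `cells` (tibble:
#'   `cell_id`, `clone_id`, `state`, `class`, `dataset_id`), `clone_barcodes`
#'   (tibble: `clone_id`, plus `barcode_id`/`barcode_seq` in STICR mode or an
#'   `integrations` list-column in TrackerSeq mode), `mode` and metadata.
#' @examples
#' lib <- gen_barcode_library(pool_sizes = c(8, 8, 8), seed = 1)
#' pop <- gen_clonal_population(n_clones = 5, clone_size = dist_constant(3),
#'                              states = c("A", "B"), library = lib, seed = 2)
#' pop$cells
#' @export
gen_clonal_population <- function(n_clones,
                                  clone_size = dist_truncgeom(mean = 3, max = 30),
                                  states = c("S1", "S2"),
                                  state_probs = NULL,
                                  mode = c("STICR", "TrackerSeq"),
                                  library = NULL,
                                  integrations_per_cell = dist_poisson1(3),
                                  tracker_mask = TRACKER_MASK_DEFAULT,
                                  classes = NULL,
                                  dataset_id = "D1",
                                  cell_barcode_length = 16L,
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (n_clones < 1L) abort("n_clones must be at least 1")
  if (length(states) < 1L) abort("at least one state label is required")
  if (mode == "STICR" && !inherits(library, "barcode_library")) {
    abort("STICR mode requires a `library` from gen_barcode_library()")
  }
  local_seed(seed)

  prob_matrix <- resolve_state_probs(state_probs, n_clones, states)
  if (is.null(classes)) {
    classes <- setNames(rep("neuron", length(states)), states)
  }
  if (!all(states %in% names(classes))) {
    abort("`classes` must name a class for every state")
  }

  sizes <- draw_dist(clone_size, n_clones)
  n_cells <- sum(sizes)
  clone_ids <- sprintf("clone_%04d", seq_len(n_clones))

  cells <- tibble(
    cell_id = random_dna_distinct(n_cells, cell_barcode_length),
    clone_id = rep(clone_ids, sizes)
  )
  clone_idx <- rep(seq_len(n_clones), sizes)
  cells$state <- vapply(clone_idx, function(i) {
    sample(states, 1L, prob = prob_matrix[i, ])
  }, character(1))
  cells$class <- unname(classes[cells$state])
  cells$dataset_id <- dataset_id

  if (mode == "STICR") {
    clone_barcodes <- draw_sticr_barcodes(n_clones, library)
    clone_barcodes$clone_id <- clone_ids
    clone_barcodes <- clone_barcodes[, c("clone_id", "barcode_id", "barcode_seq")]
  } else {
    n_int <- draw_dist(integrations_per_cell, n_clones)
    pool_needed <- sum(n_int)
    barcode_pool <- draw_tracker_barcodes(pool_needed, tracker_mask)
    splits <- rep(seq_len(n_clones), n_int)
    clone_barcodes <- tibble(
      clone_id = clone_ids,
      integrations = unname(split(barcode_pool, splits))
    )
  }

  structure(
    list(cells = cells,
         clone_barcodes = clone_barcodes,
         mode = mode,
         states = states,
         classes = classes,
         tracker_mask = if (mode == "TrackerSeq") tracker_mask else NULL,
         library_index = if (mode == "STICR") library$viral_index else NULL),
    class = "sim_population"
  )
}

resolve_state_probs <- function(state_probs, n_clones, states) {
  S <- length(states)
  if (is.null(state_probs)) state_probs <- rep(1 / S, S)
  if (is.matrix(state_probs)) {
    if (nrow(state_probs) != n_clones || ncol(state_probs) != S) {
      abort("state_probs matrix must be n_clones x length(states)")
    }
    m <- state_probs
  } else {
    if (length(state_probs) != S) {
      abort("state_probs vector must have one entry per state")
    }
    m <- matrix(state_probs, nrow = n_clones, ncol = S, byrow = TRUE)
  }
  if (any(m < 0) || any(rowSums(m) <= 0)) {
    abort("state probabilities must be non-negative with positive row sums")
  }
  m / rowSums(m)
}

draw_sticr_barcodes <- function(n, library) {
  picks <- lapply(seq_along(library$pools), function(i) {
    sample.int(length(library$pools[[i]]), n, replace = TRUE,
               prob = library$pool_weights[[i]])
  })
  frag_names <- mapply(function(pool, idx) names(pool)[idx],
                       library$pools, picks, SIMPLIFY = FALSE)
  frag_seqs <- mapply(function(pool, idx) unname(pool[idx]),
                      library$pools, picks, SIMPLIFY = FALSE)
  tibble(
    barcode_id = do.call(paste, c(frag_names, list(sep = "-"))),
    barcode_seq = do.call(paste0, frag_seqs)
  )
}

draw_tracker_barcodes <- function(n, mask) {
  ch <- strsplit(mask, "", fixed = TRUE)[[1L]]
  free <- which(ch == "N")
  if (length(free) == 0L) abort("tracker_mask must contain at least one N")
  out <- character(0)
  while (length(out) < n) {
    m <- matrix(rep(ch, n), nrow = length(ch))
    m[free, ] <- sample(DNA_BASES, length(free) * n, replace = TRUE)
    out <- unique(c(out, apply(m, 2L, paste, collapse = "")))
  }
  out[seq_len(n)]
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %s mode: %d cells in %d clones, %d states\n",
    x$mode, nrow(x$cells), nrow(x$clone_barcodes), length(x$states)
  ))
  invisible(x)
}

#' Simulate barcode sequencing reads for a clonal population
#'
#' Turns a [gen_clonal_population()] ground truth into the tabular read
#' records the clone-calling stages consume, with the noise processes that
#' the processing thresholds guard against: PCR duplication, single-base UMI
#' errors on duplicated reads, and up-to-two-base substitution errors inside
#' barcode fragments.
#'
#' Each (cell, barcode) pair yields `umi_per_molecule` distinct UMIs (tagged
#' molecules); each molecule is covered by `pcr_dups` reads. With probability
#' `umi_error_rate` a molecule with at least two reads sheds one read whose
#' UMI carries a single substitution (a PCR/sequencing error that directional
#' UMI collapse should absorb); a single-read molecule has its UMI mutated in
#' place. With probability `fragment_error_rate` a molecule's payload gains
#' 1–2 substitutions confined to one barcode fragment, which 2-mismatch
#' alignment should still resolve. `barcode_dropout` removes a (cell,
#' integration) pair entirely before read generation (TrackerSeq dropout).
#'
#' @param pop a `sim_population`.
#' @param library the `barcode_library` used to build `pop` (STICR mode).
#' @param umi_per_molecule,pcr_dups count specs ([dist_constant()] family).
#' @param umi_error_rate,fragment_error_rate,barcode_dropout probabilities in
#'   `[0, 1]`.
#' @param umi_length UMI length in nucleotides.
#' @param seed integer RNG seed.
#' @return A tibble of read records (`cell_barcode`, `umi`, `payload`,
#'   `read_count`) with attributes `mode` and, in STICR mode, `layout` (see
#'   [sticr_layout()]).
#' @examples
#' lib <- gen_barcode_library(pool_sizes = c(8, 8, 8), seed = 1)
#' pop <- gen_clonal_population(5, dist_constant(2), states = "A",
#'                              library = lib, seed = 2)
#' reads <- gen_reads(pop, lib, umi_per_molecule = dist_constant(10), seed = 3)
#' head(reads)
#' @export
gen_reads <- function(pop,
                      library = NULL,
                      umi_per_molecule = dist_constant(12),
                      pcr_dups = dist_constant(1),
                      umi_error_rate = 0,
                      fragment_error_rate = 0,
                      barcode_dropout = 0,
                      umi_length = 10L,
                      seed = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  for (r in c(umi_error_rate, fragment_error_rate, barcode_dropout)) {
    if (r < 0 || r > 1) abort("error rates must lie in [0, 1]")
  }
  if (pop$mode == "STICR") {
    if (!inherits(library, "barcode_library")) {
      abort("STICR reads require the generating `library`")
    }
    if (!identical(library$viral_index, pop$library_index)) {
      abort("population and library viral indices disagree (mode mismatch?)")
    }
  }
  local_seed(seed)

  # one row per (cell, payload sequence) molecule group
  if (pop$mode == "STICR") {
    bc <- pop$clone_barcodes
    payload_of <- setNames(paste0(bc$barcode_seq, library$viral_index),
                           bc$clone_id)
    pairs <- tibble(cell_barcode = pop$cells$cell_id,
                    payload = unname(payload_of[pop$cells$clone_id]))
    layout <- sticr_layout(
      fragment_length = library$fragment_length,
      n_fragments = length(library$pools),
      index_length = nchar(library$viral_index)
    )
    frag_region_ends <- cumsum(rep(library$fragment_length,
                                   length(library$pools)))
  } else {
    bc <- pop$clone_barcodes
    ints_of <- setNames(bc$integrations, bc$clone_id)
    pairs <- tibble(
      cell_barcode = rep(pop$cells$cell_id,
                         lengths(ints_of[pop$cells$clone_id])),
      payload = unlist(ints_of[pop$cells$clone_id], use.names = FALSE)
    )
    layout <- NULL
    frag_region_ends <- nchar(pairs$payload[1] %||% 0L)
  }

  if (barcode_dropout > 0 && nrow(pairs) > 0L) {
    pairs <- pairs[runif(nrow(pairs)) >= barcode_dropout, , drop = FALSE]
  }

  n_pairs <- nrow(pairs)
  n_umis <- draw_dist(umi_per_molecule, n_pairs)
  records <- tibble(
    cell_barcode = rep(pairs$cell_barcode, n_umis),
    payload = rep(pairs$payload, n_umis),
    umi = unlist(lapply(n_umis, random_dna_distinct, len = umi_length),
                 use.names = FALSE)
  )
  records$read_count <- draw_dist(pcr_dups, nrow(records))

  # fragment substitution errors: 1-2 subs confined to one fragment
  if (fragment_error_rate > 0 && nrow(records) > 0L) {
    hit <- which(runif(nrow(records)) < fragment_error_rate)
    if (length(hit) > 0L) {
      frag_len <- if (pop$mode == "STICR") library$fragment_length
                  else nchar(records$payload[hit[1]])
      starts <- if (pop$mode == "STICR") {
        frag_region_ends - frag_len + 1L
      } else 1L
      for (i in hit) {
        s <- if (length(starts) > 1L) sample(starts, 1L) else starts
        sub <- substr(records$payload[i], s, s + frag_len - 1L)
        substr(records$payload[i], s, s + frag_len - 1L) <-
          mutate_seq(sub, sample(1:2, 1L))
      }
    }
  }

  # UMI errors: split one duplicated read off with a 1-substitution UMI
  if (umi_error_rate > 0 && nrow(records) > 0L) {
    hit <- which(runif(nrow(records)) < umi_error_rate)
    if (length(hit) > 0L) {
      err_umi <- vapply(records$umi[hit], mutate_seq, character(1), k = 1L)
      split_off <- records$read_count[hit] >= 2L
      extra <- records[hit[split_off], , drop = FALSE]
      if (nrow(extra) > 0L) {
        extra$umi <- err_umi[split_off]
        extra$read_count <- 1L
        records$read_count[hit[split_off]] <-
          records$read_count[hit[split_off]] - 1L
      }
      records$umi[hit[!split_off]] <- err_umi[!split_off]
      records <- dplyr::bind_rows(records, extra)
    }
  }

  # merge records that collided onto the same (cell, umi, payload) triple
  records <- records |>
    dplyr::group_by(.data$cell_barcode, .data$umi, .data$payload) |>
    dplyr::summarise(read_count = sum(.data$read_count), .groups = "drop")

  structure(records, mode = pop$mode, layout = layout,
            umi_length = as.integer(umi_length),
            tracker_mask = pop$tracker_mask)
}
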