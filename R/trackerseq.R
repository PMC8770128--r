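#' Parameters for transposon integration-barcode processing
#'
#' Defaults follow the filtering scheme for transposon lineage barcodes:
#' a (cell, UMI, barcode) triple needs at least 10 supporting reads, a
#' (cell, barcode) pair needs at least 6 distinct UMIs, barcodes shorter
#' than 37 nt are discarded, and clones are cut from the average-linkage
#' dendrogram of Jaccard distances at height 0.999 (on the 1 - Jaccard
#' distance scale, so only cells sharing at least one barcode can merge).
#'
#' @param min_reads_per_triple minimum reads per (cell, UMI, barcode) triple.
#' @param min_umi_per_pair minimum distinct UMIs per (cell, barcode) pair.
#' @param cut_height dendrogram cut height in `(0, 1]`.
#' @param min_barcode_length minimum barcode length (nt).
#' @param umi_collapse_mismatch UMI collapse radius (0 = exact UMIs only).
#' @param barcode_collapse_mismatch optional Hamming radius for pre-collapsing
#'   sequencing errors in the barcodes themselves; `NULL` (default) disables
#'   the collapse.
#' @return A list of class `tracker_params`.
#' @export
tracker_params <- function(min_reads_per_triple = 10L,
                           min_umi_per_pair = 6L,
                           cut_height = 0.999,
                           min_barcode_length = 37L,
                           umi_collapse_mismatch = 0L,
                           barcode_collapse_mismatch = NULL) {
  stopifnot(min_reads_per_triple >= 1L, min_umi_per_pair >= 1L,
            cut_height > 0, cut_height <= 1, min_barcode_length >= 1L,
            umi_collapse_mismatch >= 0L)
  structure(
    list(min_reads_per_triple = as.integer(min_reads_per_triple),
         min_umi_per_pair = as.integer(min_umi_per_pair),
         cut_height = cut_height,
         min_barcode_length = as.integer(min_barcode_length),
         umi_collapse_mismatch = as.integer(umi_collapse_mismatch),
         barcode_collapse_mismatch = barcode_collapse_mismatch),
    class = "tracker_params"
  )
}

#' Filter integration-barcode records into a binary integration matrix
#'
#' Applies the read and UMI thresholds and returns the binary cells x
#' lineage-barcodes matrix of retained integrations. Barcodes shorter than
#' the minimum length are discarded first; read counts are summed per
#' (cell, UMI, barcode) triple and triples below the read threshold dropped;
#' UMIs are then deduplicated per (cell, barcode) pair and pairs below the
#' UMI threshold dropped. Cells with no surviving pair do not appear as rows.
#'
#' @param records tibble with columns `cell_id` (or `cell_barcode`), `umi`,
#'   `barcode` (or `payload`) and `read_count`.
#' @param params a [tracker_params()].
#' @return An object of class `integration_matrix`: a sparse binary matrix
#'   (`$matrix`, cells x barcodes) plus a `$funnel` tibble of per-stage
#'   record counts. An input whose records all fail the filters yields a
#'   valid 0-row matrix, not an error.
#' @export
filter_integrations <- function(records, params = tracker_params()) {
  records <- as_tibble(records)
  if ("cell_barcode" %in% names(records) && !"cell_id" %in% names(records)) {
    records <- dplyr::rename(records, cell_id = "cell_barcode")
  }
  if ("payload" %in% names(records) && !"barcode" %in% names(records)) {
    records <- dplyr::rename(records, barcode = "payload")
  }
  assert_columns(records, c("cell_id", "umi", "barcode"))
  if (!"read_count" %in% names(records)) records$read_count <- 1L

  n_in <- nrow(records)
  long_enough <- nchar(records$barcode) >= params$min_barcode_length
  records <- records[long_enough, , drop = FALSE]

  if (!is.null(params$barcode_collapse_mismatch)) {
    records$barcode <- collapse_barcodes(
      records$barcode, records$read_count, params$barcode_collapse_mismatch
    )
  }

  triples <- records |>
    dplyr::group_by(.data$cell_id, .data$umi, .data$barcode) |>
    dplyr::summarise(reads = sum(.data$read_count), .groups = "drop")
  triples_kept <- dplyr::filter(triples,
                                .data$reads >= params$min_reads_per_triple)

  pairs <- dedup_umis(
    tibble(cell_id = triples_kept$cell_id, umi = triples_kept$umi,
           barcode_id = triples_kept$barcode),
    mismatch = params$umi_collapse_mismatch
  )
  pairs_kept <- dplyr::filter(pairs,
                              .data$umi_count >= params$min_umi_per_pair)

  cells <- sort(unique(pairs_kept$cell_id))
  barcodes <- sort(unique(pairs_kept$barcode_id))
  mat <- Matrix::sparseMatrix(
    i = match(pairs_kept$cell_id, cells),
    j = match(pairs_kept$barcode_id, barcodes),
    x = 1,
    dims = c(length(cells), length(barcodes)),
    dimnames = list(cells, barcodes)
  )

  funnel <- tibble(
    stage = c("records_in", "barcode_length_ok", "triples", "triples_kept",
              "pairs", "pairs_kept"),
    n = c(n_in, nrow(records), nrow(triples), nrow(triples_kept),
          nrow(pairs), nrow(pairs_kept))
  )
  structure(list(matrix = mat, funnel = funnel, params = params),
            class = "integration_matrix")
}

# directional collapse of barcode sequences by total read support
collapse_barcodes <- function(barcodes, reads, mismatch) {
  totals <- rowsum(reads, barcodes)
  uq <- rownames(totals)
  ord <- order(-totals[, 1L], uq)
  uq <- uq[ord]
  mapping <- setNames(uq, uq)
  surviving <- character(0)
  for (b in uq) {
    hits <- surviving[nchar(surviving) == nchar(b)]
    d <- if (length(hits)) hamming_to_pool(b, hits) else integer()
    if (any(d <= mismatch)) {
      mapping[b] <- hits[which(d <= mismatch)[1L]]
    } else {
      surviving <- c(surviving, b)
    }
  }
  unname(mapping[barcodes])
}

#' @export
print.integration_matrix <- function(x, ...) {
  cat(sprintf("<integration_matrix> %d cells x %d barcodes (%d entries)\n",
              nrow(x$matrix), ncol(x$matrix), Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' @method as_tibble integration_matrix
#' @export
as_tibble.integration_matrix <- function(x, ...) {
  s <- Matrix::summary(x$matrix)
  tibble(cell_id = rownames(x$matrix)[s$i],
         barcode = colnames(x$matrix)[s$j])
}

#' Call clones from an integration matrix by Jaccard clustering
#'
#' Cells are compared by the Jaccard similarity of their integration-barcode
#' sets; agglomerative clustering with average linkage on the 1 - Jaccard
#' distance is cut at `cut_height` to yield flat clones. Cells with disjoint
#' barcode sets sit at distance 1 and can never merge below the 0.999
#' default cut, so clones group only cells that share integrations.
#'
#' @param im an [filter_integrations()] result (or a binary matrix with cell
#'   rownames).
#' @param params a [tracker_params()] (only `cut_height` is used here).
#' @param dataset_id dataset label for the clone table.
#' @return A clone table: tibble of `cell_id`, `clone_id`, `dataset_id`,
#'   with the `hclust` tree as attribute `tree` and the cut scale recorded
#'   in attribute `cut` (height on the 1 - Jaccard distance scale).
#' @export
call_clones_jaccard <- function(im, params = tracker_params(),
                                dataset_id = "D1") {
  mat <- if (inherits(im, "integration_matrix")) im$matrix else im
  if (is.null(rownames(mat))) abort("integration matrix needs cell rownames")
  n <- nrow(mat)
  if (n == 0L) abort("integration matrix has no cells")
  if (n == 1L) {
    return(structure(
      tibble(cell_id = rownames(mat), clone_id = "clone_0001",
             dataset_id = dataset_id),
      tree = NULL, cut = list(height = params$cut_height,
                              scale = "1 - Jaccard distance")
    ))
  }

  d <- jaccard_distance(mat)
  tree <- hclust(stats::as.dist(d), method = "average")
  groups <- cutree(tree, h = params$cut_height)

  structure(
    tibble(cell_id = rownames(mat),
           clone_id = sprintf("clone_%04d", unname(groups)),
           dataset_id = dataset_id),
    tree = tree,
    cut = list(height = params$cut_height, scale = "1 - Jaccard distance")
  )
}

# pairwise 1 - Jaccard over binary rows of a (sparse) matrix
jaccard_distance <- function(mat) {
  m <- Matrix::Matrix((mat != 0) * 1, sparse = TRUE)
  inter <- as.matrix(Matrix::tcrossprod(m))
  sizes <- Matrix::rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / pmax(union, 1)
  diag(d) <- 0
  d
}

#' Integration-count statistics over cells
#'
#' Fraction of cells carrying multiple transposon integrations — the property
#' that lets Jaccard clustering resolve clones sharing only part of their
#' integration sets.
#'
#' @param im an `integration_matrix` (or binary matrix).
#' @param cells optional character vector restricting to a subset of cells
#'   (must be non-empty and present in the matrix).
#' @return A one-row tibble: `n_cells`, `n_barcodes` (barcodes present in the
#'   selected rows), `frac_ge2`, `frac_ge5` (fractions of cells with at
#'   least 2 and at least 5 integrations).
#' @export
integration_stats <- function(im, cells = NULL) {
  mat <- if (inherits(im, "integration_matrix")) im$matrix else im
  if (!is.null(cells)) {
    if (length(cells) == 0L) abort("cell subset is empty")
    missing <- setdiff(cells, rownames(mat))
    if (length(missing) > 0L) {
      abort(sprintf("cells not in matrix: %s",
                    paste(head(missing, 3L), collapse = ", ")))
    }
    mat <- mat[cells, , drop = FALSE]
  }
  k <- Matrix::rowSums(mat != 0)
  tibble(
    n_cells = nrow(mat),
    n_barcodes = sum(Matrix::colSums(mat != 0) > 0),
    frac_ge2 = mean(k >= 2),
    frac_ge5 = mean(k >= 5)
  )
}

#' Count multicellular clones
#'
#' Number of clones with two or more cells, optionally after restricting the
#' clone table to an annotated cell subset (the restriction is applied before
#' sizes are computed, so a clone reduced to one cell no longer counts).
#'
#' @param clone_table tibble with `cell_id` and `clone_id`.
#' @param cells optional character vector of cells to keep.
#' @return Integer count.
#' @export
multicellular_clones <- function(clone_table, cells = NULL) {
  assert_columns(clone_table, c("cell_id", "clone_id"))
  if (!is.null(cells)) {
    clone_table <- dplyr::filter(clone_table, .data$cell_id %in% cells)
  }
  sizes <- dplyr::count(clone_table, .data$clone_id)
  sum(sizes$n >= 2L)
}
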