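#' Read and write barcode read records
#'
#' The tabular dialect is a TSV with columns `cell_barcode`, `umi`,
#' `payload`, `read_count`. The FASTQ dialect stores one record per read
#' (duplicates expanded to `read_count` copies) with the cell barcode and
#' UMI carried in the read id as `CB:<seq>` / `UMI:<seq>` tags; reading
#' collapses identical (cell, UMI, payload) reads back into counts, so a
#' write/read round trip preserves the records. An empty file yields an
#' empty read set with a warning. FASTQ support uses the Biostrings parser.
#'
#' @param path file path.
#' @param format `"tsv"` or `"fastq"`.
#' @param reads read tibble (as produced by [gen_reads()]).
#' @param mode mode attribute to attach on read (`"STICR"`/`"TrackerSeq"`),
#'   optional.
#' @return `read_reads()` returns the read tibble; `write_reads()` returns
#'   `path` invisibly.
#' @export
read_reads <- function(path, format = c("tsv", "fastq"), mode = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "tsv") {
    if (file.size(path) == 0L) {
      warn(sprintf("empty read file: %s", path))
      out <- tibble(cell_barcode = character(), umi = character(),
                    payload = character(), read_count = integer())
      return(structure(out, mode = mode))
    }
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             cell_barcode = "c", umi = "c", payload = "c",
                             read_count = "i"
                           ))
    assert_columns(out, c("cell_barcode", "umi", "payload", "read_count"))
    return(structure(as_tibble(out), mode = mode))
  }

  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTQ requires the Biostrings package")
  }
  if (file.size(path) == 0L) {
    warn(sprintf("empty read file: %s", path))
    return(structure(
      tibble(cell_barcode = character(), umi = character(),
             payload = character(), read_count = integer()),
      mode = mode
    ))
  }
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    abort(sprintf(
      "malformed FASTQ at %s: record %d is truncated (%d lines total)",
      path, n_lines %/% 4L + 1L, n_lines
    ))
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      abort(sprintf("malformed FASTQ at %s: %s", path, conditionMessage(e)))
    }
  )
  ids <- names(seqs)
  cb <- stringr::str_match(ids, "CB:([ACGTN]+)")[, 2L]
  umi <- stringr::str_match(ids, "UMI:([ACGTN]+)")[, 2L]
  bad <- which(is.na(cb) | is.na(umi))
  if (length(bad) > 0L) {
    abort(sprintf("FASTQ record %d lacks CB:/UMI: tags in its id", bad[1L]))
  }
  tibble(cell_barcode = cb, umi = umi,
         payload = as.character(seqs)) |>
    dplyr::count(.data$cell_barcode, .data$umi, .data$payload,
                 name = "read_count") |>
    structure(mode = mode)
}

#' @rdname read_reads
#' @export
write_reads <- function(reads, path, format = c("tsv", "fastq")) {
  format <- match.arg(format)
  assert_columns(reads, c("cell_barcode", "umi", "payload", "read_count"))
  if (format == "tsv") {
    readr::write_tsv(reads[, c("cell_barcode", "umi", "payload",
                               "read_count")], path)
    return(invisible(path))
  }
  idx <- rep(seq_len(nrow(reads)), reads$read_count)
  ids <- sprintf("@read%07d CB:%s UMI:%s", seq_along(idx),
                 reads$cell_barcode[idx], reads$umi[idx])
  qual <- strrep("I", nchar(reads$payload[idx]))
  writeLines(rbind(ids, reads$payload[idx], "+", qual), path)
  invisible(path)
}

#' Read and write expression matrices
#'
#' `"mtx_dir"` expects (or creates) a directory in the common droplet layout
#' — `matrix.mtx` (MatrixMarket, genes x cells), `features.tsv` (gene ids)
#' and `barcodes.tsv` (cell ids). `"csv"` stores a dense matrix with genes
#' as the first column. Duplicated gene or cell names and empty matrices
#' are errors.
#'
#' @param path directory (`mtx_dir`) or file (`csv`) path.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param expr genes x cells matrix with dimnames.
#' @return `read_expression_matrix()` returns a dense genes x cells matrix;
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    feats <- file.path(path, "features.tsv")
    cells <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feats, cells)) {
      if (!file.exists(f)) abort(sprintf("missing file: %s", f))
    }
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readr::read_tsv(feats, col_names = "gene",
                             show_col_types = FALSE)$gene
    barcodes <- readr::read_tsv(cells, col_names = "cell",
                                show_col_types = FALSE)$cell
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      abort("matrix dimensions disagree with features/barcodes files")
    }
    dimnames(m) <- list(genes, barcodes)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    genes <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- genes
  }
  if (nrow(m) == 0L || ncol(m) == 0L) abort("empty expression matrix")
  if (anyDuplicated(rownames(m))) abort("duplicated gene names")
  if (anyDuplicated(colnames(m))) abort("duplicated cell names")
  m
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(expr, path,
                                    format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("expression matrix needs gene rownames and cell colnames")
  }
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(gene = rownames(expr)),
                     file.path(path, "features.tsv"), col_names = FALSE)
    readr::write_tsv(tibble(cell = colnames(expr)),
                     file.path(path, "barcodes.tsv"), col_names = FALSE)
  } else {
    df <- dplyr::bind_cols(tibble(gene = rownames(expr)),
                           as_tibble(as.data.frame(expr)))
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read and write cell annotations
#'
#' CSV with columns `cell_id`, plus any of `clone_id`, `state`, `class`,
#' `dataset_id`, `cluster`.
#'
#' @param path file path.
#' @param annotation annotation tibble.
#' @return `read_annotation()` returns a tibble; `write_annotation()`
#'   returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(out, "cell_id")
  as_tibble(out)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  readr::write_csv(annotation, path)
  invisible(path)
}

#' Read fragment pools from plain-text files
#'
#' Each pool file lists one fragment sequence per line, optionally preceded
#' by a fragment id and a tab; unnamed fragments are numbered in file order.
#'
#' @param paths character vector of pool file paths, in pool order.
#' @param viral_indices known viral-index sequences.
#' @return A [fragment_reference()].
#' @export
read_fragment_pools <- function(paths, viral_indices = character()) {
  pools <- lapply(seq_along(paths), function(i) {
    lines <- readLines(paths[[i]])
    lines <- lines[nzchar(lines)]
    parts <- stringr::str_split_fixed(lines, "\t", 2L)
    has_id <- nzchar(parts[, 2L])
    seqs <- ifelse(has_id, parts[, 2L], parts[, 1L])
    ids <- ifelse(has_id, parts[, 1L],
                  sprintf("P%d_F%03d", i, seq_along(lines)))
    setNames(seqs, ids)
  })
  fragment_reference(pools, viral_indices)
}
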