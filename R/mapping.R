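#' Build postnatal cell-type model vectors
#'
#' Averages log-normalized expression per postnatal cluster over the shared
#' variable-gene list, producing one model vector per cluster — the targets
#' of correlation-based developmental mapping.
#'
#' @param expr genes x cells matrix of log-normalized expression with gene
#'   rownames and cell colnames.
#' @param labels tibble with `cell_id` and `cluster` covering the matrix
#'   columns, or a named character vector (cell -> cluster).
#' @param genes shared variable-gene list (must all be present in `expr`).
#' @return An object of class `model_vectors`: `vectors` (genes x clusters
#'   matrix of cluster means), `genes`, `clusters`.
#' @export
build_model_vectors <- function(expr, labels, genes = rownames(expr)) {
  labels <- as_label_vector(labels, colnames(expr))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    abort(sprintf("gene(s) absent from matrix: %s",
                  paste(head(missing, 3L), collapse = ", ")))
  }
  clusters <- sort(unique(labels))
  empty <- clusters[!clusters %in% labels]
  if (length(empty) > 0L) abort("every cluster needs at least one cell")

  m <- expr[genes, , drop = FALSE]
  vectors <- vapply(clusters, function(cl) {
    rowMeans(m[, labels == cl, drop = FALSE])
  }, numeric(length(genes)))
  dimnames(vectors) <- list(genes, clusters)
  if (any(!is.finite(vectors))) abort("model vectors must be finite")
  structure(list(vectors = vectors, genes = genes, clusters = clusters),
            class = "model_vectors")
}

as_label_vector <- function(labels, cell_ids) {
  if (is.data.frame(labels)) {
    assert_columns(labels, c("cell_id", "cluster"))
    labels <- setNames(labels$cluster, labels$cell_id)
  }
  if (is.null(names(labels))) abort("labels must be named by cell id")
  missing <- setdiff(cell_ids, names(labels))
  if (length(missing) > 0L) {
    abort(sprintf("cells without a cluster label: %s",
                  paste(head(missing, 3L), collapse = ", ")))
  }
  unname(labels[cell_ids])
}

#' Correlate embryonic cells with postnatal model vectors
#'
#' Computes the Pearson correlation of each embryonic cell with every model
#' vector over the shared gene list and assigns the cell to the cluster with
#' the highest correlation. Ties are broken by the first cluster in declared
#' order and flagged; cells with zero expression variance over the genes
#' cannot be correlated and are flagged unmapped.
#'
#' @param expr genes x cells embryonic expression matrix (log-normalized).
#' @param models a [build_model_vectors()] result.
#' @return A tibble per cell: `cell_id`, `best_cluster`, `best_r`, `tie`,
#'   `zero_variance`; the full cells x clusters correlation matrix is
#'   attached as attribute `r_matrix`.
#' @export
map_cells <- function(expr, models) {
  stopifnot(inherits(models, "model_vectors"))
  missing <- setdiff(models$genes, rownames(expr))
  if (length(missing) > 0L) {
    abort(sprintf("expression matrix lacks model gene(s): %s",
                  paste(head(missing, 3L), collapse = ", ")))
  }
  m <- expr[models$genes, , drop = FALSE]
  zero_var <- apply(m, 2L, sd) == 0
  r <- suppressWarnings(cor(m, models$vectors))  # cells x clusters

  best_idx <- unname(apply(r, 1L, function(row) {
    if (all(is.na(row))) NA_integer_ else which.max(row)
  }))
  tie <- unname(apply(r, 1L, function(row) {
    if (all(is.na(row))) FALSE else sum(row == max(row, na.rm = TRUE)) > 1L
  }))

  out <- tibble(
    cell_id = colnames(expr),
    best_cluster = ifelse(is.na(best_idx), NA_character_,
                          models$clusters[best_idx]),
    best_r = ifelse(is.na(best_idx), NA_real_,
                    r[cbind(seq_len(nrow(r)), best_idx)]),
    tie = tie,
    zero_variance = unname(zero_var)
  )
  attr(out, "r_matrix") <- r
  out
}

#' Empirical p-values for cluster assignments
#'
#' Builds a random background for each cell's best correlation: the model
#' vectors stay fixed while the single-cell expression is permuted `n_perm`
#' times. Under the default `"within_cell"` scheme each cell's values are
#' shuffled across genes independently (preserving the cell's expression
#' distribution); `"within_gene"` shuffles each gene across cells instead.
#' For each permutation and cell the largest correlation to any model vector
#' is recorded, and the p-value is the fraction of permuted maxima strictly
#' larger than the observed best correlation — so p = 0 is possible at the
#' default 100 permutations.
#'
#' @param expr genes x cells embryonic expression matrix.
#' @param models a [build_model_vectors()] result.
#' @param assignments a [map_cells()] result (recomputed when `NULL`).
#' @param n_perm number of permutations (default 100).
#' @param scheme permutation unit, `"within_cell"` (default) or
#'   `"within_gene"`.
#' @param seed integer RNG seed.
#' @return The `assignments` tibble with an added `p_emp` column; the scheme
#'   is recorded in attribute `perm_scheme`.
#' @export
empirical_pvalues <- function(expr, models, assignments = NULL,
                              n_perm = 100L,
                              scheme = c("within_cell", "within_gene"),
                              seed = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 1L) abort("n_perm must be at least 1")
  if (is.null(assignments)) assignments <- map_cells(expr, models)
  local_seed(seed)

  m <- expr[models$genes, , drop = FALSE]
  g <- nrow(m)
  n_cells <- ncol(m)
  exceed <- integer(n_cells)
  for (b in seq_len(n_perm)) {
    perm <- if (scheme == "within_cell") {
      # shuffle every column over genes independently
      idx <- vapply(seq_len(n_cells), function(j) sample.int(g),
                    integer(g))
      matrix(m[cbind(as.vector(idx), rep(seq_len(n_cells), each = g))],
             nrow = g)
    } else {
      t(apply(m, 1L, sample))
    }
    r <- suppressWarnings(cor(perm, models$vectors))
    max_r <- apply(r, 1L, function(row) {
      if (all(is.na(row))) -Inf else max(row, na.rm = TRUE)
    })
    exceed <- exceed + (max_r > assignments$best_r)
  }
  assignments$p_emp <- ifelse(is.na(assignments$best_r), NA_real_,
                              exceed / n_perm)
  attr(assignments, "perm_scheme") <- scheme
  attr(assignments, "n_perm") <- as.integer(n_perm)
  assignments
}

#' Gate assignments by Benjamini-Hochberg false discovery rate
#'
#' Converts empirical p-values to BH-adjusted FDR values and flags as mapped
#' only the cells with FDR below the threshold.
#'
#' @param p numeric vector of p-values (NAs stay unmapped) or a tibble with
#'   a `p_emp` column.
#' @param threshold FDR threshold (default 0.1; gate is strict `<`).
#' @return For vector input, a tibble of `p_emp`, `fdr`, `mapped`; for
#'   tibble input, the tibble with `fdr` and `mapped` columns added.
#' @export
fdr_gate <- function(p, threshold = 0.1) {
  df <- NULL
  if (is.data.frame(p)) {
    df <- p
    assert_columns(df, "p_emp")
    p <- df$p_emp
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  fdr <- p.adjust(p, method = "BH")
  mapped <- !is.na(fdr) & fdr < threshold
  if (is.null(df)) {
    tibble(p_emp = p, fdr = fdr, mapped = mapped)
  } else {
    df$fdr <- fdr
    df$mapped <- mapped
    df
  }
}

#' Map embryonic cells to postnatal clusters with permutation FDR
#'
#' End-to-end wrapper: correlation assignment ([map_cells()]), empirical
#' p-values against permuted expression ([empirical_pvalues()]) and FDR
#' gating ([fdr_gate()]).
#'
#' @param expr genes x cells embryonic expression matrix.
#' @param models a [build_model_vectors()] result.
#' @param n_perm permutations for the empirical p-values.
#' @param fdr_threshold FDR gate (strict `<`).
#' @param scheme permutation scheme (see [empirical_pvalues()]).
#' @param seed integer RNG seed.
#' @return An object of class `mapping_result`: the per-cell tibble
#'   (`cell_id`, `best_cluster`, `best_r`, `tie`, `zero_variance`, `p_emp`,
#'   `fdr`, `mapped`) with parameters in attribute `params`.
#' @examples
#' pair <- gen_expression_pair(n_genes = 80, cells_per_cluster = 10, seed = 1)
#' mv <- build_model_vectors(pair$postnatal$expr, pair$postnatal$labels)
#' res <- map_embryonic_cells(pair$embryonic$expr, mv, n_perm = 20, seed = 2)
#' table(res$best_cluster, res$mapped)
#' @export
map_embryonic_cells <- function(expr, models, n_perm = 100L,
                                fdr_threshold = 0.1,
                                scheme = c("within_cell", "within_gene"),
                                seed = NULL) {
  scheme <- match.arg(scheme)
  assignments <- map_cells(expr, models)
  assignments <- empirical_pvalues(expr, models, assignments,
                                   n_perm = n_perm, scheme = scheme,
                                   seed = seed)
  out <- fdr_gate(assignments, fdr_threshold)
  attr(out, "params") <- list(n_perm = as.integer(n_perm),
                              fdr_threshold = fdr_threshold,
                              perm_scheme = scheme, seed = seed)
  class(out) <- c("mapping_result", class(out))
  out
}

#' Mapping fractions per embryonic cluster
#'
#' Among the mapped cells of each embryonic cluster, the fraction assigned
#' to each postnatal cluster. Rows sum to 1; embryonic clusters with no
#' mapped cell report `NA` fractions and are flagged in attribute
#' `no_mapped_cells`.
#'
#' @param result a [map_embryonic_cells()] result (or any tibble with
#'   `cell_id`, `best_cluster`, `mapped`).
#' @param labels embryonic labels: tibble of `cell_id`, `cluster` or a named
#'   vector.
#' @return A tibble: `embryonic_cluster`, `postnatal_cluster`, `n_cells`,
#'   `fraction`.
#' @export
mapping_fractions <- function(result, labels) {
  assert_columns(result, c("cell_id", "best_cluster", "mapped"))
  lab <- as_label_vector(labels, result$cell_id)
  df <- tibble(embryonic_cluster = lab,
               postnatal_cluster = result$best_cluster,
               mapped = result$mapped)

  mapped_counts <- df |>
    dplyr::filter(.data$mapped) |>
    dplyr::count(.data$embryonic_cluster, .data$postnatal_cluster,
                 name = "n_cells") |>
    dplyr::group_by(.data$embryonic_cluster) |>
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()

  empty <- setdiff(unique(lab), mapped_counts$embryonic_cluster)
  if (length(empty) > 0L) {
    mapped_counts <- dplyr::bind_rows(
      mapped_counts,
      tibble(embryonic_cluster = empty, postnatal_cluster = NA_character_,
             n_cells = 0L, fraction = NA_real_)
    )
  }
  structure(dplyr::arrange(mapped_counts, .data$embryonic_cluster),
            no_mapped_cells = empty)
}

#' Spearman correlation distance between cluster expression profiles
#'
#' Distance between clusters defined as 1 minus the Spearman rank
#' correlation of their average log-normalized expression vectors. Clusters
#' with a constant average vector have undefined rank correlations; their
#' distances are `NA` and the clusters are flagged in attribute `constant`.
#'
#' @param expr genes x cells matrix of log-normalized expression.
#' @param labels tibble of `cell_id`, `cluster` or named vector.
#' @return A symmetric distance matrix (zero diagonal) over the clusters.
#' @export
cluster_distance_spearman <- function(expr, labels) {
  labels <- as_label_vector(labels, colnames(expr))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) abort("at least 2 clusters are required")
  avg <- vapply(clusters, function(cl) {
    rowMeans(expr[, labels == cl, drop = FALSE])
  }, numeric(nrow(expr)))
  constant <- apply(avg, 2L, sd) == 0
  d <- 1 - suppressWarnings(cor(avg, method = "spearman"))
  diag(d) <- 0
  dimnames(d) <- list(clusters, clusters)
  structure(d, constant = clusters[constant])
}
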