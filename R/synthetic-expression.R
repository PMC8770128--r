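#' Generate a matched embryonic/postnatal expression-matrix pair
#'
#' Simulates two log-normalized expression matrices — an "embryonic" and a
#' "postnatal" dataset — whose matched clusters share elevated marker genes,
#' the structure that correlation-based developmental mapping relies on. Each
#' postnatal cluster receives a disjoint set of `n_marker_per_cluster` marker
#' genes whose mean expression is raised by `effect` (log-normalized units) in
#' that cluster and in its matched embryonic cluster; all other values sit at
#' a gene-specific baseline. Gaussian noise with sd `noise_sd` is added and
#' values are clamped at zero, so matrices stay on a non-negative
#' log-normalized scale.
#'
#' With `noise_sd = 0` every embryonic cell correlates maximally with its
#' matched postnatal model vector; with `effect = 0` mapping accuracy falls to
#' chance (1 / number of clusters).
#'
#' @param cluster_map named character vector: embryonic cluster label ->
#'   matched postnatal cluster label.
#' @param n_genes total number of genes (must cover all marker sets).
#' @param n_marker_per_cluster markers per postnatal cluster (disjoint sets).
#' @param effect marker elevation in log-normalized units (> 0, or 0 for a
#'   null dataset).
#' @param noise_sd Gaussian noise sd.
#' @param cells_per_cluster cells per cluster in each dataset.
#' @param baseline_range range of the per-gene baseline means (uniform).
#'   The default gives every gene its own baseline, the realistic regime in
#'   which all cells share a gene-level expression profile; a degenerate
#'   range such as `c(1, 1)` makes cells pure noise around a flat baseline,
#'   the regime in which correlation to any model vector is uninformative.
#' @param seed integer RNG seed.
#' @return A list with elements `embryonic` and `postnatal` (each a list with
#'   `expr`, a genes x cells matrix, and `labels`, a tibble of `cell_id` and
#'   `cluster`), `genes` (the shared variable-gene list, here all genes) and
#'   `markers` (tibble: `gene`, `postnatal_cluster`).
#' @examples
#' pair <- gen_expression_pair(n_genes = 60, cells_per_cluster = 5, seed = 1)
#' dim(pair$embryonic$expr)
#' @export
gen_expression_pair <- function(cluster_map = setNames(paste0("P", 1:5),
                                                       paste0("E", 1:5)),
                                n_genes = 500L,
                                n_marker_per_cluster = 20L,
                                effect = 2,
                                noise_sd = 0.5,
                                cells_per_cluster = 100L,
                                baseline_range = c(0.1, 1.5),
                                seed = NULL) {
  if (is.null(names(cluster_map)) || anyDuplicated(names(cluster_map)) ||
      anyDuplicated(cluster_map)) {
    abort("cluster_map must be a named vector with unique names and values")
  }
  if (effect < 0) abort("effect must be non-negative")
  k <- length(cluster_map)
  total_markers <- k * n_marker_per_cluster
  if (n_genes < total_markers) {
    abort(sprintf("n_genes (%d) is smaller than the %d marker genes required",
                  n_genes, total_markers))
  }
  local_seed(seed)

  genes <- sprintf("gene%04d", seq_len(n_genes))
  baseline <- runif(n_genes, baseline_range[1], baseline_range[2])
  post_clusters <- unname(cluster_map)
  marker_idx <- split(seq_len(total_markers),
                      rep(seq_len(k), each = n_marker_per_cluster))

  make_matrix <- function(cluster_labels, prefix) {
    n_cells <- k * cells_per_cluster
    mean_mat <- matrix(baseline, nrow = n_genes, ncol = n_cells)
    cl_of_cell <- rep(seq_len(k), each = cells_per_cluster)
    for (j in seq_len(k)) {
      mean_mat[marker_idx[[j]], cl_of_cell == j] <-
        mean_mat[marker_idx[[j]], cl_of_cell == j] + effect
    }
    expr <- mean_mat
    if (noise_sd > 0) {
      expr <- expr + matrix(rnorm(length(expr), sd = noise_sd),
                            nrow = n_genes)
    }
    expr <- pmax(expr, 0)
    cell_ids <- sprintf("%s_cell%04d", prefix, seq_len(n_cells))
    dimnames(expr) <- list(genes, cell_ids)
    list(expr = expr,
         labels = tibble(cell_id = cell_ids,
                         cluster = cluster_labels[cl_of_cell]))
  }

  list(
    embryonic = make_matrix(names(cluster_map), "emb"),
    postnatal = make_matrix(post_clusters, "post"),
    genes = genes,
    markers = tibble(
      gene = genes[seq_len(total_markers)],
      postnatal_cluster = rep(post_clusters, each = n_marker_per_cluster)
    ),
    cluster_map = cluster_map
  )
}
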