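#' Shared-clone coupling metric for one pair of cell states
#'
#' For a clone with `n` cells, let `k` be the number of its cells assigned to
#' either state of the pair. The clone is *shared* between the two states if
#' `k >= 2` and at least one cell sits in each state; the pair's metric is
#' the sum over shared clones of `p = k / n`, the fraction of each shared
#' clone captured by the pair. The metric is symmetric in the two states and
#' bounded by the number of clones spanning both.
#'
#' @param clone_table tibble with `cell_id` and `clone_id`.
#' @param annotation tibble with `cell_id` and `state` covering every cell in
#'   the clone table.
#' @param s1,s2 two distinct state labels.
#' @return The metric, a single non-negative number.
#' @examples
#' ct <- tibble::tibble(cell_id = as.character(1:4),
#'                      clone_id = c("c1", "c1", "c2", "c2"))
#' ann <- tibble::tibble(cell_id = as.character(1:4),
#'                       state = c("A", "B", "A", "A"))
#' pair_metric(ct, ann, "A", "B")  # clone c1: k = n = 2, p = 1
#' @export
pair_metric <- function(clone_table, annotation, s1, s2) {
  dat <- join_states(clone_table, annotation)
  states <- unique(dat$state)
  for (s in c(s1, s2)) {
    if (!s %in% states) abort(sprintf("unknown state label '%s'", s))
  }
  if (identical(s1, s2)) abort("pair_metric requires two distinct states")
  dat |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      k1 = sum(.data$state == s1),
      k2 = sum(.data$state == s2),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k1 >= 1L, .data$k2 >= 1L) |>
    dplyr::summarise(m = sum((.data$k1 + .data$k2) / .data$n)) |>
    dplyr::pull(.data$m)
}

join_states <- function(clone_table, annotation, require_class = FALSE) {
  assert_columns(clone_table, c("cell_id", "clone_id"))
  assert_columns(annotation, c("cell_id", "state"))
  dat <- dplyr::inner_join(
    clone_table,
    dplyr::distinct(annotation, .data$cell_id, .keep_all = TRUE),
    by = "cell_id"
  )
  if (nrow(dat) < nrow(clone_table)) {
    abort("some cells in the clone table have no state annotation")
  }
  if (require_class) {
    if (!"class" %in% names(dat) || anyNA(dat$class)) {
      abort("every cell needs a class annotation")
    }
  }
  dat
}

#' Lineage coupling z-scores over all state pairs
#'
#' Quantifies whether pairs of cell states share clones more (or less) than
#' expected by chance. The observed shared-clone metric (see [pair_metric()])
#' is compared to a permutation null: for each of `n_perm` iterations the
#' state assignments of individual cells are shuffled, preserving the number
#' of cells per state exactly, and the metric is recomputed for every pair.
#' The z-score of a pair is its observed metric standardised by the null mean
#' and (population) standard deviation; positive values mean the pair shares
#' more lineage barcodes than chance. Pairs whose null is degenerate
#' (sd = 0, e.g. all clones singletons) report z = 0 and are flagged.
#'
#' The coupling correlation of two states — the Pearson correlation between
#' their z-score vectors against all other states — is computed alongside
#' (see [coupling_correlations()]).
#'
#' @param clone_table tibble with `cell_id` and `clone_id`.
#' @param annotation tibble with `cell_id`, `state`.
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer RNG seed for the permutation stream.
#' @param states optional ordered state set to report (defaults to the
#'   sorted states present).
#' @return An object of class `coupling_result`: symmetric matrices
#'   `observed`, `null_mean`, `null_sd`, `z`, `corr` over the states
#'   (diagonal `NA`; the metric is defined only for pairs of distinct
#'   states), a logical `degenerate` matrix flagging sd-zero pairs, plus
#'   `n_perm` and `seed`.
#' @examples
#' ct <- tibble::tibble(cell_id = as.character(1:6),
#'                      clone_id = rep(c("c1", "c2", "c3"), each = 2))
#' ann <- tibble::tibble(cell_id = as.character(1:6),
#'                       state = c("A", "B", "A", "B", "A", "B"))
#' res <- coupling_zscores(ct, ann, n_perm = 200, seed = 1)
#' res$z
#' @export
coupling_zscores <- function(clone_table, annotation, n_perm = 10000L,
                             seed = NULL, states = NULL) {
  if (n_perm < 2L) abort("n_perm must be at least 2")
  dat <- join_states(clone_table, annotation)
  states <- states %||% sort(unique(dat$state))
  if (length(states) < 2L) abort("at least 2 states are required")
  if (!all(dat$state %in% states)) {
    abort("`states` must cover every annotated state in the clone table")
  }
  if (nrow(dat) < length(states)) abort("fewer cells than states")
  local_seed(seed)

  clone_idx <- match(dat$clone_id, unique(dat$clone_id))
  state_idx <- match(dat$state, states)
  n_clones <- max(clone_idx)
  S <- length(states)
  inv_n <- 1 / tabulate(clone_idx, n_clones)

  observed <- metric_matrix(clone_idx, state_idx, n_clones, S, inv_n)

  sum_m <- matrix(0, S, S)
  sum_m2 <- matrix(0, S, S)
  for (b in seq_len(n_perm)) {
    perm <- sample(state_idx)  # one global shuffle serves all pairs
    m <- metric_matrix(clone_idx, perm, n_clones, S, inv_n)
    sum_m <- sum_m + m
    sum_m2 <- sum_m2 + m * m
  }
  null_mean <- sum_m / n_perm
  null_sd <- sqrt(pmax(sum_m2 / n_perm - null_mean^2, 0))

  degenerate <- null_sd == 0
  z <- ifelse(degenerate, 0, (observed - null_mean) / null_sd)
  diag(observed) <- diag(null_mean) <- diag(null_sd) <- diag(z) <- NA_real_
  diag(degenerate) <- NA
  dimnames(observed) <- dimnames(null_mean) <- dimnames(null_sd) <-
    dimnames(z) <- dimnames(degenerate) <- list(states, states)

  res <- structure(
    list(states = states, observed = observed, null_mean = null_mean,
         null_sd = null_sd, z = z, corr = NULL, degenerate = degenerate,
         n_perm = as.integer(n_perm), seed = seed,
         n_cells = nrow(dat), n_clones = n_clones),
    class = "coupling_result"
  )
  res$corr <- coupling_correlations(res)
  res
}

# metric for all state pairs at once:
# M(a,b) = sum over clones with cells in both a and b of (C[,a]+C[,b])/n_c.
# With A = (C > 0) this is X + t(X) where X = t(C/n) %*% A, because a clone
# contributes C[,a]/n via X[a,b] and C[,b]/n via X[b,a] exactly when both
# states are present (k >= 2 is implied by presence in both states).
metric_matrix <- function(clone_idx, state_idx, n_clones, S, inv_n) {
  C <- matrix(
    tabulate(clone_idx + n_clones * (state_idx - 1L), n_clones * S),
    nrow = n_clones, ncol = S
  )
  A <- C > 0
  X <- crossprod(C * inv_n, A)
  X + t(X)
}

#' Lineage coupling correlations
#'
#' The coupling correlation of a state pair is the Pearson correlation
#' between the two states' vectors of coupling z-scores to all states,
#' excluding the diagonal entries and the pair's own entry (so a pair is not
#' correlated with itself through its shared coordinate). Pairs with a
#' constant z-vector have no defined correlation and are reported as 0 with
#' a flag in attribute `undefined`.
#'
#' @param result a [coupling_zscores()] result.
#' @return A symmetric correlation matrix over the states (diagonal 1).
#' @export
coupling_correlations <- function(result) {
  stopifnot(inherits(result, "coupling_result"))
  z <- result$z
  S <- length(result$states)
  corr <- matrix(1, S, S, dimnames = dimnames(z))
  undefined <- matrix(FALSE, S, S, dimnames = dimnames(z))
  for (a in seq_len(S - 1L)) {
    for (b in (a + 1L):S) {
      idx <- setdiff(seq_len(S), c(a, b))
      za <- z[a, idx]
      zb <- z[b, idx]
      if (length(idx) < 2L || sd(za) == 0 || sd(zb) == 0) {
        corr[a, b] <- corr[b, a] <- 0
        undefined[a, b] <- undefined[b, a] <- TRUE
      } else {
        corr[a, b] <- corr[b, a] <- cor(za, zb)
      }
    }
  }
  structure(corr, undefined = undefined)
}

#' Lineage dendrogram from coupling correlations
#'
#' Hierarchically clusters cell states by the Euclidean distance between
#' their rows of the coupling-correlation matrix, with average linkage, and
#' optionally cuts the tree into flat clonal groups.
#'
#' @param corr symmetric coupling-correlation matrix (e.g. `result$corr`).
#' @param k number of flat groups to cut (optional).
#' @param h cut height (optional alternative to `k`).
#' @return A list with `tree` (an `hclust`) and, when `k` or `h` is given,
#'   `groups` (tibble of `state`, `group`).
#' @export
lineage_dendrogram <- function(corr, k = NULL, h = NULL) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    abort("corr must be a square matrix")
  }
  if (nrow(corr) < 2L) abort("at least 2 states are required")
  m <- corr
  diag(m) <- 1
  tree <- hclust(dist(m, method = "euclidean"), method = "average")
  out <- list(tree = tree, groups = NULL)
  if (!is.null(k) || !is.null(h)) {
    cuts <- cutree(tree, k = k, h = h)
    out$groups <- tibble(state = names(cuts), group = unname(cuts))
  }
  out
}

#' Classify clones by cell-class composition
#'
#' For every clone, the dominant class fraction (largest share of a single
#' cell class) and two categorisations: purity — `"100%"` when all cells
#' share one class, `">80%"` when the dominant fraction lies strictly
#' between 0.8 and 1, `"<80%"` otherwise (a fraction of exactly 0.8 falls in
#' `"<80%"`); and lineage — `glia_only` (only glial classes among
#' glia/neuron cells), `neuron_only`, `mixed` (both), or `other` for clones
#' containing neither neurons nor glia (e.g. purely vascular clones), which
#' are excluded from the three-way glia/neuron split and counted separately.
#'
#' @param clone_table tibble with `cell_id`, `clone_id` and optionally
#'   `dataset_id`.
#' @param annotation tibble with `cell_id`, `state` and `class` for every
#'   cell (a clone containing an unclassed cell is an error).
#' @param glia_classes,neuron_classes class labels counted as glia / neurons.
#' @return A tibble per clone: `clone_id`, `dataset_id`, `n_cells`,
#'   `dominant_class`, `dominant_fraction`, `purity_category`,
#'   `lineage_category`.
#' @seealso [composition_fractions()] for per-dataset category fractions.
#' @export
clone_composition <- function(clone_table, annotation,
                              glia_classes = c("astrocyte", "OPC",
                                               "oligodendrocyte"),
                              neuron_classes = "neuron") {
  dat <- join_states(clone_table, annotation, require_class = TRUE)
  if (!"dataset_id" %in% names(dat)) dat$dataset_id <- "all"

  dat |>
    dplyr::group_by(.data$dataset_id, .data$clone_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      dominant_class = names(which.max(table(.data$class))),
      dominant_fraction = max(table(.data$class)) / dplyr::n(),
      has_glia = any(.data$class %in% glia_classes),
      has_neuron = any(.data$class %in% neuron_classes),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      purity_category = dplyr::case_when(
        .data$dominant_fraction == 1 ~ "100%",
        .data$dominant_fraction > 0.8 ~ ">80%",
        TRUE ~ "<80%"
      ),
      lineage_category = dplyr::case_when(
        .data$has_glia & .data$has_neuron ~ "mixed",
        .data$has_glia ~ "glia_only",
        .data$has_neuron ~ "neuron_only",
        TRUE ~ "other"
      )
    ) |>
    dplyr::select(-"has_glia", -"has_neuron")
}

#' Per-dataset clone-category fractions
#'
#' Fractions of clones per purity category and per lineage category within
#' each dataset, relative to the clones eligible for each categorisation
#' (`other` clones are excluded from the glia/neuron denominators and
#' reported as their own row).
#'
#' @param composition a [clone_composition()] result.
#' @return A tibble: `dataset_id`, `categorisation` (`"purity"` or
#'   `"lineage"`), `category`, `n_clones`, `fraction`.
#' @export
composition_fractions <- function(composition) {
  assert_columns(composition,
                 c("dataset_id", "purity_category", "lineage_category"))
  purity <- composition |>
    dplyr::count(.data$dataset_id, category = .data$purity_category,
                 name = "n_clones") |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(categorisation = "purity",
                  fraction = .data$n_clones / sum(.data$n_clones)) |>
    dplyr::ungroup()
  lineage <- composition |>
    dplyr::count(.data$dataset_id, category = .data$lineage_category,
                 name = "n_clones") |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(
      categorisation = "lineage",
      fraction = .data$n_clones /
        sum(.data$n_clones[.data$category != "other"])
    ) |>
    dplyr::ungroup()
  dplyr::bind_rows(purity, lineage) |>
    dplyr::select("dataset_id", "categorisation", "category", "n_clones",
                  "fraction")
}

#' Clone intersections over selected states (UpSet counts)
#'
#' Maps each clone to the set of selected states it occupies and tallies
#' clones per distinct state set — the input of an UpSet plot. Clones
#' occupying none of the selected states are dropped; with
#' `dispersing_only = TRUE` (default) clones occupying fewer than two
#' selected states are dropped as well, leaving only dispersing clones.
#' Set sizes are the number of cells per selected state.
#'
#' @param clone_table tibble with `cell_id`, `clone_id`.
#' @param annotation tibble with `cell_id`, `state`.
#' @param selected_states non-empty subset of the annotated states.
#' @param dispersing_only drop clones occupying fewer than 2 selected states.
#' @return A list with `intersections` (tibble: `state_set` — labels joined
#'   by `"&"` in `selected_states` order, `states` — list-column, `n_clones`)
#'   and `set_sizes` (tibble: `state`, `n_cells`).
#' @export
clone_intersections <- function(clone_table, annotation, selected_states,
                                dispersing_only = TRUE) {
  if (length(selected_states) == 0L) abort("selected_states is empty")
  dat <- join_states(clone_table, annotation)
  unknown <- setdiff(selected_states, unique(annotation$state))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown state(s): %s", paste(unknown, collapse = ", ")))
  }

  sets <- dat |>
    dplyr::filter(.data$state %in% selected_states) |>
    dplyr::distinct(.data$clone_id, .data$state) |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      states = list(selected_states[selected_states %in% .data$state]),
      n_states = dplyr::n(),
      .groups = "drop"
    )
  if (dispersing_only) {
    sets <- dplyr::filter(sets, .data$n_states >= 2L)
  }
  intersections <- sets |>
    dplyr::mutate(state_set = vapply(.data$states, paste, character(1),
                                     collapse = "&")) |>
    dplyr::group_by(.data$state_set) |>
    dplyr::summarise(states = .data$states[1L],
                     n_clones = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_clones))

  set_sizes <- dat |>
    dplyr::filter(.data$state %in% selected_states) |>
    dplyr::count(.data$state, name = "n_cells")

  list(intersections = intersections, set_sizes = set_sizes)
}
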