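# Independent reference implementations used to check the package's
# computations. These deliberately use the most literal algorithm available
# (per-clone loops, exhaustive enumeration, O(n^3) clustering) rather than
# the package's vectorised paths.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# literal shared-clone metric: loop over clones, apply the definition
oracle_pair_metric <- function(clone_table, ann, s1, s2) {
  state_of <- setNames(ann$state, ann$cell_id)
  total <- 0
  for (cl in unique(clone_table$clone_id)) {
    cells <- clone_table$cell_id[clone_table$clone_id == cl]
    st <- state_of[cells]
    k <- sum(st %in% c(s1, s2))
    if (k >= 2 && any(st == s1) && any(st == s2)) {
      total <- total + k / length(cells)
    }
  }
  total
}

# all distinct arrangements of a label multiset over positions
unique_permutations <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (lab in unique(remaining)) {
      idx <- match(lab, remaining)
      recurse(c(prefix, lab), remaining[-idx])
    }
  }
  recurse(character(0), labels)
  out
}

# exact permutation-null moments of the pair metric by full enumeration
oracle_exact_null <- function(clone_table, ann, s1, s2) {
  arrangements <- unique_permutations(ann$state)
  vals <- vapply(arrangements, function(st) {
    ann2 <- ann
    ann2$state <- st
    oracle_pair_metric(clone_table, ann2, s1, s2)
  }, numeric(1))
  list(mean = mean(vals), sd = sqrt(mean(vals^2) - mean(vals)^2),
       values = vals)
}

# literal UPGMA: merge the pair of clusters with the smallest average
# pairwise distance until that minimum exceeds the cut height
oracle_average_linkage_cut <- function(d, h) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d) {
          best_d <- avg
          best <- c(i, j)
        }
      }
    }
    if (best_d > h) break
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  membership <- integer(n)
  for (g in seq_along(clusters)) membership[clusters[[g]]] <- g
  membership
}

# literal Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# quick clone table + annotation builders for hand instances
make_clone_table <- function(clone_sizes, dataset_id = "D1") {
  clone_id <- rep(sprintf("c%02d", seq_along(clone_sizes)), clone_sizes)
  tibble::tibble(
    cell_id = sprintf("cell%03d", seq_along(clone_id)),
    clone_id = clone_id,
    dataset_id = dataset_id
  )
}

make_annotation <- function(clone_table, states, classes = NULL) {
  ann <- tibble::tibble(cell_id = clone_table$cell_id, state = states)
  if (!is.null(classes)) ann$class <- classes
  ann
}

# random clonal instance for property checks; every state is guaranteed to
# appear at least once so state labels are always queryable
random_instance <- function(n_clones, max_size, states, seed) {
  withr::with_seed(seed, {
    sizes <- sample.int(max_size, n_clones, replace = TRUE)
    n <- sum(sizes)
    stopifnot(n >= length(states))
    labels <- c(states, sample(states, n - length(states), replace = TRUE))
    ct <- make_clone_table(sizes)
    ann <- make_annotation(ct, sample(labels))
    list(clone_table = ct, annotation = ann)
  })
}
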