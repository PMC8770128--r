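#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a coupling result into a pair-level tibble
#'
#' One row per unordered state pair: observed metric, null moments, z-score,
#' coupling correlation and the degenerate-null flag.
#'
#' @param x a [coupling_zscores()] result.
#' @param ... unused.
#' @return A tibble with columns `state1`, `state2`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `corr`, `degenerate`.
#' @method tidy coupling_result
#' @export
tidy.coupling_result <- function(x, ...) {
  S <- length(x$states)
  pairs <- which(upper.tri(x$z), arr.ind = TRUE)
  tibble(
    state1 = x$states[pairs[, 1L]],
    state2 = x$states[pairs[, 2L]],
    observed = x$observed[pairs],
    null_mean = x$null_mean[pairs],
    null_sd = x$null_sd[pairs],
    z = x$z[pairs],
    corr = x$corr[pairs],
    degenerate = x$degenerate[pairs]
  )
}

#' @describeIn tidy.coupling_result one-row summary: dimensions, permutation
#'   count, z-score range and number of degenerate pairs.
#' @method glance coupling_result
#' @export
glance.coupling_result <- function(x, ...) {
  z <- x$z[upper.tri(x$z)]
  tibble(
    n_states = length(x$states),
    n_cells = x$n_cells,
    n_clones = x$n_clones,
    n_perm = x$n_perm,
    min_z = min(z),
    max_z = max(z),
    n_degenerate = sum(x$degenerate[upper.tri(x$degenerate)])
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    "<coupling_result> %d states, %d cells in %d clones, %d permutations\n",
    length(x$states), x$n_cells, x$n_clones, x$n_perm
  ))
  z <- x$z[upper.tri(x$z)]
  cat(sprintf("  z range: [%.2f, %.2f]; degenerate pairs: %d\n",
              min(z), max(z),
              sum(x$degenerate[upper.tri(x$degenerate)])))
  invisible(x)
}

#' Tidy methods for mapping results
#'
#' `tidy()` returns the per-cell assignment tibble; `glance()` a one-row
#' summary with the mapped fraction.
#'
#' @param x a [map_embryonic_cells()] result.
#' @param ... unused.
#' @method tidy mapping_result
#' @export
tidy.mapping_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "mapping_result")
  out
}

#' @describeIn tidy.mapping_result one-row summary.
#' @method glance mapping_result
#' @export
glance.mapping_result <- function(x, ...) {
  params <- attr(x, "params")
  tibble(
    n_cells = nrow(x),
    n_mapped = sum(x$mapped),
    frac_mapped = mean(x$mapped),
    median_best_r = stats::median(x$best_r, na.rm = TRUE),
    n_perm = params$n_perm,
    fdr_threshold = params$fdr_threshold
  )
}
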