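#' Expected number of unique barcodes among n labelled cells
#'
#' Closed form for the expectation of the number of distinct barcodes drawn
#' when `n` cells each receive one barcode independently from a library:
#' `sum_i (1 - (1 - p_i)^n)` over barcode abundances `p_i`. For a uniform
#' library of size `D` this is `D * (1 - (1 - 1/D)^n)`, evaluated with
#' `expm1`/`log1p` so it stays exact for very large `D`. The expected number
#' of collisions is `n` minus this value.
#'
#' @param n number of labelled cells (vectorised).
#' @param abundances barcode abundance vector (non-negative, summing to 1
#'   within 1e-9), or `NULL` for a uniform library.
#' @param library_size library size `D` (required when `abundances` is
#'   `NULL`).
#' @return Expected unique-barcode count, one value per element of `n`.
#' @examples
#' expected_unique(2, abundances = c(0.5, 0.5))  # 1.5
#' expected_unique(100, library_size = 1000)
#' @export
expected_unique <- function(n, abundances = NULL, library_size = NULL) {
  stopifnot(all(n >= 0))
  if (is.null(abundances)) {
    if (is.null(library_size) || library_size < 1) {
      abort("supply `abundances` or a positive `library_size`")
    }
    D <- as.numeric(library_size)
    return(-D * expm1(n * log1p(-1 / D)))
  }
  check_abundances(abundances)
  vapply(n, function(nn) sum(-expm1(nn * log1p(-abundances))), numeric(1))
}

check_abundances <- function(p) {
  if (any(p < 0)) abort("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) abort("abundances must sum to 1 (tol 1e-9)")
  invisible(p)
}

#' Monte-Carlo simulation of lineage-barcode collisions
#'
#' Simulates labelling a starting population of `n` cells with barcodes drawn
#' independently (with replacement) from the library, and records the number
#' of unique barcodes per replicate. The collision count of a replicate is
#' exactly `n` minus its unique count. Replicates for large populations are
#' scaled down to keep the total number of draws near `draw_budget`; such
#' rows carry `scaled_down = TRUE` and their Monte-Carlo standard error is
#' reported alongside.
#'
#' @param library_size library size `D` (ignored when `abundances` given).
#' @param population_sizes labelled-population sizes to simulate (default
#'   `10^(1:6)`, log-spaced).
#' @param n_reps replicates per population size (default 20,000, before
#'   budget scaling).
#' @param abundances optional explicit abundance vector (length `D`); `NULL`
#'   means uniform.
#' @param draw_budget approximate per-size cap on `n * replicates`.
#' @param seed integer RNG seed.
#' @return A tibble of class `collision_curve`: `n_cells`, `mean_unique`,
#'   `mean_collisions`, `se` (standard error of the mean unique count),
#'   `n_reps_used`, `scaled_down`, `expected_unique` (the closed form).
#' @examples
#' simulate_collisions(1000, population_sizes = c(10, 100), n_reps = 200,
#'                     seed = 1)
#' @export
simulate_collisions <- function(library_size,
                                population_sizes = 10^(1:6),
                                n_reps = 20000L,
                                abundances = NULL,
                                draw_budget = 2e7,
                                seed = NULL) {
  if (n_reps < 2L) abort("n_reps must be at least 2")
  stopifnot(all(population_sizes >= 1))
  if (!is.null(abundances)) {
    check_abundances(abundances)
    library_size <- length(abundances)
  }
  stopifnot(library_size >= 1)
  local_seed(seed)

  rows <- lapply(sort(population_sizes), function(n) {
    reps <- min(n_reps, max(100L, ceiling(draw_budget / n)))
    uniques <- vapply(seq_len(reps), function(i) {
      draws <- if (is.null(abundances)) {
        sample.int(library_size, n, replace = TRUE)
      } else {
        sample.int(library_size, n, replace = TRUE, prob = abundances)
      }
      length(unique(draws))
    }, numeric(1))
    tibble(
      n_cells = n,
      mean_unique = mean(uniques),
      mean_collisions = n - mean(uniques),
      se = sd(uniques) / sqrt(reps),
      n_reps_used = reps,
      scaled_down = reps < n_reps
    )
  })

  out <- dplyr::bind_rows(rows)
  out$expected_unique <- expected_unique(out$n_cells, abundances,
                                         library_size)
  class(out) <- c("collision_curve", class(out))
  attr(out, "library_size") <- library_size
  attr(out, "uniform") <- is.null(abundances)
  attr(out, "seed") <- seed
  out
}
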