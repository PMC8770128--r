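#' Discrete distribution specifications for the synthetic generators
#'
#' Small declarative specs for the count distributions the generators draw
#' from (clone sizes, integrations per clone, UMIs per molecule, PCR
#' duplicates per UMI). Keeping them as data rather than closures lets a run
#' configuration round-trip through YAML.
#'
#' * `dist_constant(value)` — every draw equals `value`.
#' * `dist_truncgeom(mean, max)` — geometric on 1, 2, ... with the given mean,
#'   truncated at `max` (draws above `max` are redrawn). The default clone-size
#'   model: many small clones, few large ones.
#' * `dist_poisson1(lambda)` — 1 + Poisson(lambda), for counts that must be
#'   at least 1 (e.g. transposon integrations per clone).
#' * `dist_empirical(values, probs)` — categorical over the given values.
#'
#' @param value,mean,max,lambda,values,probs distribution parameters.
#' @return A list of class `count_dist` describing the distribution.
#' @examples
#' draw_dist(dist_constant(3), 5)
#' mean(draw_dist(dist_truncgeom(mean = 3, max = 30), 1e4))
#' @export
dist_constant <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 1)
  structure(list(kind = "constant", value = as.integer(value)),
            class = "count_dist")
}

#' @rdname dist_constant
#' @export
dist_truncgeom <- function(mean, max = Inf) {
  stopifnot(mean > 1, max >= mean)
  structure(list(kind = "truncgeom", mean = mean, max = max),
            class = "count_dist")
}

#' @rdname dist_constant
#' @export
dist_poisson1 <- function(lambda) {
  stopifnot(lambda >= 0)
  structure(list(kind = "poisson1", lambda = lambda), class = "count_dist")
}

#' @rdname dist_constant
#' @export
dist_empirical <- function(values, probs = NULL) {
  stopifnot(length(values) >= 1L, all(values >= 1))
  if (is.null(probs)) probs <- rep(1 / length(values), length(values))
  stopifnot(length(probs) == length(values), all(probs >= 0), sum(probs) > 0)
  structure(list(kind = "empirical", values = as.integer(values),
                 probs = probs / sum(probs)),
            class = "count_dist")
}

#' Draw from a count distribution specification
#'
#' @param dist a [dist_constant()]-family spec.
#' @param n number of draws.
#' @return An integer vector of length `n`, all values `>= 1`.
#' @export
draw_dist <- function(dist, n) {
  stopifnot(inherits(dist, "count_dist"), n >= 0)
  if (n == 0L) return(integer())
  switch(dist$kind,
    constant = rep(dist$value, n),
    truncgeom = {
      # geometric on 1,2,... with mean m has success prob 1/m
      p <- 1 / dist$mean
      out <- rgeom(n, p) + 1L
      while (any(bad <- out > dist$max)) {
        out[bad] <- rgeom(sum(bad), p) + 1L
      }
      out
    },
    poisson1 = rpois(n, dist$lambda) + 1L,
    empirical = sample(dist$values, n, replace = TRUE, prob = dist$probs),
    abort(sprintf("unknown distribution kind '%s'", dist$kind))
  )
}
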