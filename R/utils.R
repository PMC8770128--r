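#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor dist hclust cutree p.adjust rnorm runif rgeom rpois sd setNames
#' @importFrom utils head modifyList packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

# n random DNA sequences of the given length (not guaranteed distinct)
random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  apply(m, 2L, paste, collapse = "")
}

# n distinct random DNA sequences
random_dna_distinct <- function(n, len) {
  if (4^len < n) {
    abort(sprintf("cannot draw %d distinct sequences of length %d", n, len))
  }
  out <- unique(random_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), len)))
  }
  out
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Hamming distances from one query string to each string in a pool
# (all equal length). Byte comparison; pools are small (<= a few hundred).
hamming_to_pool <- function(query, pool) {
  qa <- charToRaw(query)
  len <- length(qa)
  pm <- matrix(charToRaw(paste(pool, collapse = "")), nrow = len)
  colSums(pm != qa)
}

# substitute k random positions of a DNA string with different bases
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# set the RNG seed for the calling frame and restore the previous state on exit
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
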