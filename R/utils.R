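# Seed plumbing: every stochastic operation takes an explicit seed and
# restores the caller's RNG state, so package calls never perturb a user's
# random stream and sub-streams can be derived deterministically by name.

withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Derive a named deterministic sub-seed
#'
#' Hashes a root seed together with arbitrary labels (stage names, retention
#' fractions, method names) into a new 31-bit seed, so that all randomness in
#' a pipeline flows from one root seed through named sub-streams.
#'
#' @param seed integer root seed.
#' @param ... labels (characters or numbers) identifying the sub-stream.
#' @return A single integer in \[1, 2^31 - 2\].
#' @examples
#' subSeed(42, "thin", 0.5)
#' @export
subSeed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "\r")
  h <- 11L
  m <- 2147483647
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer(h %% (m - 2L)) + 1L
}

#' Canonical unordered pair key
#'
#' @param a,b individual identifiers (vectorised).
#' @return Character key `"<min>|<max>"`, identical for both orderings.
#' @examples
#' pairKey("B", "A")
#' @export
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# all unordered pairs of a character vector, as a 2-column matrix
allPairs <- function(ids) {
  if (length(ids) < 2) stop("need at least two individuals")
  t(combn(ids, 2))
}

# classify a statistic by nearest theoretical expectation, boundaries at
# midpoints between adjacent expectations; `expected` must be sorted
# decreasing and named by degree label
classifyNearest <- function(x, expected) {
  cuts <- (expected[-length(expected)] + expected[-1]) / 2
  idx <- findInterval(-x, -cuts) + 1L   # 1 = largest expectation
  out <- names(expected)[idx]
  out[is.na(x)] <- NA_character_
  out
}

# degree label from a kinship coefficient (phi scale)
degreeFromPhi <- function(phi) {
  expected <- c(identical = 0.5, first = 0.25, second = 0.125,
                third = 0.0625, unrelated = 0)
  classifyNearest(phi, expected)
}

# delete-one jackknife standard error of a mean
jackknifeSE <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  loo <- (sum(x) - x) / (n - 1)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Round coverage for report parity
#'
#' Mean coverages are computed at full precision; reports conventionally
#' print them at two decimals (e.g. 1.06x, 0.53x).
#'
#' @param x numeric coverage value(s).
#' @return `x` rounded to 2 decimals.
#' @export
roundCoverage <- function(x) round(x, 2)
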