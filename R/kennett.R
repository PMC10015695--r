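#' Genome-wide pairwise mismatch rates
#'
#' For every unordered pair, the proportion of shared non-missing
#' pseudohaploid calls that differ, over the whole panel (no windows), with
#' the shared-site count recorded. Pairs with zero shared sites get `NA`
#' and are flagged downstream.
#'
#' @param ph a `PseudohaploidCalls` with >= 2 individuals.
#' @return A list of class `kennett_mismatch` with symmetric matrices `m`
#'   (mismatch rate) and `n_shared`.
#' @export
kennettMismatch <- function(ph) {
  C <- phCalls(ph)
  if (ncol(C) < 2) stop("need at least two individuals")
  ids <- colnames(C)
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ns <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- !is.na(C[, i]) & !is.na(C[, j])
    ns[i, j] <- ns[j, i] <- sum(sh)
    if (ns[i, j] > 0)
      m[i, j] <- m[j, i] <- sum(C[sh, i] != C[sh, j]) / ns[i, j]
  }
  structure(list(m = m, n_shared = ns), class = "kennett_mismatch")
}

#' Significance screen on mismatch rates
#'
#' The highest observed mismatch rate is taken as that of an unrelated
#' pair. Each pair's rate is tested against it with a two-sample binomial z
#' statistic,
#' `z = (m_max - m) / sqrt(m (1 - m) / n_shared + se_max^2)`,
#' and the cohort is declared to contain relatives only when some z exceeds
#' a Bonferroni-adjusted threshold whose base level is `z_screen` (i.e.
#' a per-pair tail probability of `pnorm(-z_screen) / n_pairs`). Because the
#' screened statistic is the gap between each pair and the observed maximum
#' of all pairs, multiplicity control is what keeps all-unrelated cohorts
#' from triggering the screen by chance. If no pair deviates significantly,
#' the whole cohort is assumed to contain no relatives — the guard that
#' prevents over-prediction when the maximum-rate normalisation is applied
#' to an all-unrelated group.
#'
#' @param mm output of [kennettMismatch()] with >= 3 pairs.
#' @param z_screen base significance threshold (default 3.0).
#' @return A list: `any_relatives` (logical), `z` (symmetric matrix of
#'   per-pair z values), `m_max`, `z_screen`, `z_crit` (the adjusted
#'   threshold actually applied).
#' @export
kennettScreen <- function(mm, z_screen = 3.0) {
  stopifnot(inherits(mm, "kennett_mismatch"))
  n <- nrow(mm$m)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs < 3) stop("screen needs at least 3 pairs")
  imax <- which(mm$m == max(mm$m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  m_max <- mm$m[imax[1], imax[2]]
  se2_max <- m_max * (1 - m_max) / mm$n_shared[imax[1], imax[2]]
  se <- sqrt(mm$m * (1 - mm$m) / mm$n_shared + se2_max)
  z <- (m_max - mm$m) / se
  z[!is.na(mm$m) & se == 0] <- ifelse(mm$m[!is.na(mm$m) & se == 0] < m_max,
                                      Inf, 0)
  diag(z) <- NA
  z_crit <- qnorm(pnorm(-z_screen) / n_pairs, lower.tail = FALSE)
  list(any_relatives = any(z > z_crit, na.rm = TRUE), z = z,
       m_max = m_max, z_screen = z_screen, z_crit = z_crit)
}

#' Max-rate-normalised relatedness coefficients
#'
#' Normalises each pair's mismatch rate by the maximum observed rate (or a
#' user-supplied normalisation value): `r = 2 (1 - m / m_max)`, which has
#' expectation `2 phi` (1 for an identical pair, 0.5 first degree, 0.25
#' second, 0.125 third, 0 unrelated). Degrees are assigned by nearest
#' expectation with midpoint boundaries. With `apply_screen = TRUE` and a
#' screen reporting no relatives, every pair is reported unrelated
#' regardless of r; switching the screen off reproduces the characteristic
#' over-prediction of this normalisation on all-unrelated cohorts.
#'
#' @param mm output of [kennettMismatch()].
#' @param screen output of [kennettScreen()] (computed if `NULL`).
#' @param apply_screen honour the screen's no-relatives verdict.
#' @param norm_value optional manual normalisation value replacing the
#'   observed maximum mismatch rate.
#' @return A data.frame per pair: `pair`, `m`, `n_shared`, `r`, `z_vs_max`,
#'   `degree`, `related`, `flag`.
#' @export
kennettR <- function(mm, screen = NULL, apply_screen = TRUE,
                     norm_value = NULL) {
  stopifnot(inherits(mm, "kennett_mismatch"))
  if (is.null(screen)) screen <- kennettScreen(mm)
  m_max <- if (is.null(norm_value)) max(mm$m, na.rm = TRUE) else norm_value
  if (!is.finite(m_max) || m_max <= 0)
    stop("degenerate mismatch matrix: maximum mismatch rate is 0")
  ids <- rownames(mm$m)
  prs <- allPairs(ids)
  m <- mm$m[cbind(prs[, 1], prs[, 2])]
  ns <- mm$n_shared[cbind(prs[, 1], prs[, 2])]
  r <- 2 * (1 - m / m_max)
  expected <- c(identical = 1, first = 0.5, second = 0.25,
                third = 0.125, unrelated = 0)
  degree <- classifyNearest(r, expected)
  flag <- ifelse(is.na(m), "insufficient", "ok")
  related <- flag == "ok" & degree %in% c("identical", "first", "second")
  if (apply_screen && !screen$any_relatives) {
    related[] <- FALSE
    degree[flag == "ok"] <- "unrelated"
  }
  data.frame(pair = pairKey(prs[, 1], prs[, 2]), m = m, n_shared = ns,
             r = r, z_vs_max = screen$z[cbind(prs[, 1], prs[, 2])],
             degree = degree, related = related, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}
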