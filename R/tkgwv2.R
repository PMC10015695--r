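#' Allele-frequency-based halved relatedness coefficients (HRC)
#'
#' Over the shared non-missing pseudohaploid calls of a pair, with
#' `S_s = 1` when the two haploid calls agree and
#' `u_s = p_s^2 + (1 - p_s)^2` the agreement probability expected for an
#' unrelated pair under the supplied population allele frequencies, the
#' halved relatedness coefficient is
#' `hrc = sum(S_s - u_s) / sum(1 - u_s)`.
#' For outbred pairs its expectation is the kinship coefficient phi (0.25
#' first degree, 0.125 second, 0 unrelated). Because expected agreement is
#' taken from the frequency panel rather than the cohort, far fewer shared
#' sites are needed than for cohort-normalised estimators — but frequencies
#' unrepresentative of the population bias the estimate systematically.
#'
#' @param ph a `PseudohaploidCalls`.
#' @param freqs per-site population alternative-allele frequencies, strictly
#'   inside (0, 1); defaults to the panel's `alt_freq`.
#' @param min_sites minimum shared sites per pair (default 500); pairs
#'   below it are flagged `insufficient` and never called related.
#' @param related_min HRC threshold for the binary related call (default
#'   0.09375, the midpoint between the second- and third-degree
#'   expectations).
#' @return A data.frame per pair: `pair`, `hrc`, `n_shared`, `degree`,
#'   `related`, `flag`.
#' @export
hrcEstimate <- function(ph, freqs = altFreq(ph), min_sites = 500,
                        related_min = 0.09375) {
  C <- phCalls(ph)
  if (ncol(C) < 2) stop("need at least two individuals")
  if (length(freqs) != nrow(C))
    stop("freqs must have one value per panel site")
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  u <- freqs^2 + (1 - freqs)^2
  prs <- allPairs(colnames(C))
  hrc <- n_sh <- numeric(nrow(prs))
  for (k in seq_len(nrow(prs))) {
    ci <- C[, prs[k, 1]]; cj <- C[, prs[k, 2]]
    sh <- !is.na(ci) & !is.na(cj)
    n_sh[k] <- sum(sh)
    hrc[k] <- if (n_sh[k] > 0)
      sum((ci[sh] == cj[sh]) - u[sh]) / sum(1 - u[sh]) else NA_real_
  }
  expected <- c(identical = 0.5, first = 0.25, second = 0.125,
                third = 0.0625, unrelated = 0)
  flag <- ifelse(n_sh >= min_sites, "ok", "insufficient")
  data.frame(pair = pairKey(prs[, 1], prs[, 2]), hrc = hrc,
             n_shared = n_sh, degree = classifyNearest(hrc, expected),
             related = flag == "ok" & !is.na(hrc) & hrc >= related_min,
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}
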