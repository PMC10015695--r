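#' Allele-sharing summary statistics (R0, R1, KING)
#'
#' Accumulates the joint genotype class masses
#' `X(a, b) += post_i(a) * post_j(b)` over co-covered sites, where the
#' per-site genotype posterior is the likelihood triple weighted by its
#' Hardy--Weinberg prior at the site's allele frequency. From the masses:
#' `IBS0 = X(0,2) + X(2,0)` (opposing homozygotes), `HETHET = X(1,1)`,
#' `HET_i`/`HET_j` the heterozygote masses of each individual, and
#'
#' * `r0 = IBS0 / HETHET`
#' * `r1 = HETHET / (IBS0 + X(0,1) + X(1,0) + X(1,2) + X(2,1))`
#' * `king = (HETHET - 2 * IBS0) / (HET_i + HET_j)`
#'
#' Degrees follow the standard powers-of-two KING bins (identical
#' > 0.354, first (0.177, 0.354], second (0.0884, 0.177], third
#' (0.0442, 0.0884]); a pair is related when `king >= 0.0884`.
#'
#' @param gl a `GLMatrix`.
#' @param pair character vector of two individual ids.
#' @param freqs per-site alternative-allele frequencies (default: panel's).
#' @param min_sites minimum co-covered sites (default 500).
#' @return A list: `pair`, `X` (3x3 mass matrix), `ibs0`, `hethet`, `r0`,
#'   `r1`, `king`, `n_sites`, `degree`, `related`, `flag`.
#' @export
alleleSharingStats <- function(gl, pair, freqs = altFreq(gl),
                               min_sites = 500) {
  L <- likelihoods(gl)
  i <- pair[1]; j <- pair[2]
  cov <- !is.na(L$L1[, i]) & !is.na(L$L1[, j])
  n_used <- sum(cov)
  empty <- list(pair = sort(pair), X = matrix(NA_real_, 3, 3),
                ibs0 = NA_real_, hethet = NA_real_, r0 = NA_real_,
                r1 = NA_real_, king = NA_real_, n_sites = n_used,
                degree = NA_character_, related = FALSE,
                flag = "insufficient")
  if (n_used < min_sites) return(empty)
  p <- freqs[cov]; q <- 1 - p
  H <- cbind(q^2, 2 * p * q, p^2)
  Pi <- cbind(L$L0[cov, i], L$L1[cov, i], L$L2[cov, i]) * H
  Pj <- cbind(L$L0[cov, j], L$L1[cov, j], L$L2[cov, j]) * H
  Pi <- Pi / rowSums(Pi)
  Pj <- Pj / rowSums(Pj)
  X <- crossprod(Pi, Pj)                    # X[a+1, b+1], masses sum to n
  ibs0 <- X[1, 3] + X[3, 1]
  hethet <- X[2, 2]
  het_i <- X[2, 1] + X[2, 2] + X[2, 3]
  het_j <- X[1, 2] + X[2, 2] + X[3, 2]
  r0 <- if (hethet > 0) ibs0 / hethet else NA_real_
  r1_den <- ibs0 + X[1, 2] + X[2, 1] + X[2, 3] + X[3, 2]
  r1 <- if (hethet > 0 && r1_den > 0) hethet / r1_den else NA_real_
  king <- if (het_i + het_j > 0) (hethet - 2 * ibs0) / (het_i + het_j)
          else NA_real_
  cuts <- c(0.3536, 0.1768, 0.0884, 0.0442)  # powers-of-two KING bins
  degree <- if (is.na(king)) NA_character_
            else DEGREE_LEVELS[findInterval(-king, -cuts) + 1L]
  list(pair = sort(pair), X = X, ibs0 = ibs0, hethet = hethet, r0 = r0,
       r1 = r1, king = king, n_sites = n_used, degree = degree,
       related = !is.na(king) && king >= 0.0884, flag = "ok")
}

#' All-pairs allele-sharing statistics
#'
#' @inheritParams alleleSharingStats
#' @param ... passed to [alleleSharingStats()].
#' @return A data.frame per pair: `pair`, `ibs0`, `hethet`, `r0`, `r1`,
#'   `king`, `n_sites`, `degree`, `related`, `flag`.
#' @export
pairwiseKing <- function(gl, freqs = altFreq(gl), ...) {
  prs <- allPairs(colnames(gl))
  rows <- lapply(seq_len(nrow(prs)), function(r) {
    s <- alleleSharingStats(gl, prs[r, ], freqs, ...)
    data.frame(pair = pairKey(prs[r, 1], prs[r, 2]), ibs0 = s$ibs0,
               hethet = s$hethet, r0 = s$r0, r1 = s$r1, king = s$king,
               n_sites = s$n_sites, degree = s$degree, related = s$related,
               flag = s$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
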