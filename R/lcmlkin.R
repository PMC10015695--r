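#' IBD-conditional joint genotype tables
#'
#' The three 3x3 tables giving the joint probability of a pair's diploid
#' genotypes (alt-allele counts 0/1/2) conditional on sharing m = 0, 1 or 2
#' alleles identical by descent, at a biallelic site with alternative-allele
#' frequency p under Hardy--Weinberg equilibrium. m = 0 is the product of
#' HWE margins; m = 2 the diagonal HWE; m = 1 a HWE margin times the
#' one-shared-allele transition.
#'
#' @param p alternative-allele frequency in (0, 1).
#' @return List of matrices `T0`, `T1`, `T2`, each summing to 1.
#' @examples
#' tt <- ibdJointTables(0.5)
#' tt$T0[2, 2]   # (2pq)^2 = 0.25
#' @export
ibdJointTables <- function(p) {
  if (length(p) != 1 || p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  q <- 1 - p
  h <- c(q^2, 2 * p * q, p^2)
  trans <- rbind(c(q, p, 0),
                 c(q / 2, 1 / 2, p / 2),
                 c(0, q, p))
  list(T0 = outer(h, h), T1 = h * trans, T2 = diag(h))
}

# per-site mixture components A[s, m+1] = sum_{gi,gj} Li Lj T_m(gi,gj|p_s),
# vectorised over sites; Li/Lj are n x 3, p length n
ibdSiteComponents <- function(Li, Lj, p) {
  q <- 1 - p
  H <- cbind(q^2, 2 * p * q, p^2)
  ai <- rowSums(Li * H)
  aj <- rowSums(Lj * H)
  A0 <- ai * aj
  A2 <- rowSums(Li * Lj * H)
  A1 <- Li[, 1] * H[, 1] * (Lj[, 1] * q + Lj[, 2] * p) +
        Li[, 2] * H[, 2] * (Lj[, 1] * q / 2 + Lj[, 2] / 2 + Lj[, 3] * p / 2) +
        Li[, 3] * H[, 3] * (Lj[, 2] * q + Lj[, 3] * p)
  cbind(A0, A1, A2, deparse.level = 0)
}

#' Kinship coefficient from IBD coefficients
#'
#' `phi = k1 / 4 + k2 / 2`: (0, 1, 0) gives 0.25 (parent--offspring),
#' (1, 0, 0) gives 0 (unrelated), (0, 0, 1) gives 0.5 (identical genomes).
#'
#' @param k numeric vector (k0, k1, k2) on the probability simplex.
#' @return The kinship coefficient.
#' @export
phiFromK <- function(k) {
  stopifnot(length(k) == 3, all(k >= -1e-9), abs(sum(k) - 1) < 1e-6)
  unname(k[2] / 4 + k[3] / 2)
}

#' Maximum-likelihood IBD coefficients from genotype likelihoods
#'
#' Maximises, over the (k0, k1, k2) probability simplex, the composite
#' log-likelihood
#' `sum_s log sum_m k_m * A_m(s)` with
#' `A_m(s) = sum_{gi,gj} L_i(gi) L_j(gj) T_m(gi, gj | p_s)`,
#' via EM treating the IBD class m as latent (E-step: posterior over m per
#' site; M-step: k_m = mean posterior). The log-likelihood is asserted
#' non-decreasing at every iteration. Three starts are run — the unrelated
#' vertex, the parent--offspring-like interior point and the barycentre —
#' and the best kept. The kinship coefficient is `phi = k1/4 + k2/2`.
#'
#' @param gl a `GLMatrix`.
#' @param pair character vector of two individual ids.
#' @param freqs per-site alternative-allele frequencies (default: panel's).
#' @param min_sites minimum co-covered sites (default 500); below it an
#'   insufficient-data result is returned rather than an error.
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param starts list of simplex starting points.
#' @return A list: `pair`, `k` (named k0/k1/k2), `phi`, `n_sites`,
#'   `loglik`, `converged`, `flag` ("ok" or "insufficient").
#' @export
mlKEstimate <- function(gl, pair, freqs = altFreq(gl), min_sites = 500,
                        tol = 1e-6, max_iter = 500,
                        starts = list(c(1, 0, 0), c(0.25, 0.5, 0.25),
                                      c(1, 1, 1) / 3)) {
  L <- likelihoods(gl)
  i <- pair[1]; j <- pair[2]
  cov <- !is.na(L$L1[, i]) & !is.na(L$L1[, j])
  n_used <- sum(cov)
  if (n_used < min_sites)
    return(list(pair = sort(pair), k = c(k0 = NA, k1 = NA, k2 = NA),
                phi = NA_real_, n_sites = n_used, loglik = NA_real_,
                converged = FALSE, flag = "insufficient"))
  Li <- cbind(L$L0[cov, i], L$L1[cov, i], L$L2[cov, i])
  Lj <- cbind(L$L0[cov, j], L$L1[cov, j], L$L2[cov, j])
  A <- ibdSiteComponents(Li, Lj, freqs[cov])
  best <- NULL
  for (k0 in starts) {
    fit <- emSimplex(A, k0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  k <- setNames(best$k, c("k0", "k1", "k2"))
  list(pair = sort(pair), k = k, phi = phiFromK(k), n_sites = n_used,
       loglik = best$loglik, converged = best$converged, flag = "ok")
}

emSimplex <- function(A, k, tol, max_iter) {
  .em_simplex_cpp(A, k / sum(k), tol, max_iter)
}

#' All-pairs ML kinship
#'
#' Runs [mlKEstimate()] for every unordered pair and assigns degrees by
#' nearest kinship expectation (0.5, 0.25, 0.125, 0.0625, 0) with midpoint
#' boundaries; a pair is related when its degree is second or closer.
#'
#' @inheritParams mlKEstimate
#' @param ... passed to [mlKEstimate()].
#' @return A data.frame per pair: `pair`, `k0`, `k1`, `k2`, `phi`,
#'   `n_sites`, `loglik`, `converged`, `degree`, `related`, `flag`.
#' @export
pairwiseML <- function(gl, freqs = altFreq(gl), ...) {
  prs <- allPairs(colnames(gl))
  rows <- lapply(seq_len(nrow(prs)), function(r) {
    fit <- mlKEstimate(gl, prs[r, ], freqs, ...)
    data.frame(pair = pairKey(prs[r, 1], prs[r, 2]),
               k0 = unname(fit$k[1]), k1 = unname(fit$k[2]),
               k2 = unname(fit$k[3]), phi = fit$phi, n_sites = fit$n_sites,
               loglik = fit$loglik, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$degree <- degreeFromPhi(out$phi)
  out$flag <- ifelse(is.na(out$phi), "insufficient", "ok")
  out$related <- out$flag == "ok" &
    out$degree %in% c("identical", "first", "second")
  out
}
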