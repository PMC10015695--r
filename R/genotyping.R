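#' Random-read pseudohaploid genotype calling
#'
#' At each site with depth d >= 1 the allelic state of one uniformly drawn
#' read is used as a haploid call — alternative with probability
#' `n_alt / d` — and sites with no reads are missing. Random draw (rather
#' than majority consensus) is the standard choice for degraded data because
#' it avoids reference bias.
#'
#' @param pileup a `ReadPileup`.
#' @param seed integer seed (calls are deterministic given it).
#' @return A `PseudohaploidCalls` object (0 ref / 1 alt / NA missing).
#' @examples
#' panel <- simulatePanel(100, seed = 1)
#' g <- simulateGenotypes(panel, pedigreeUnrelated(2), seed = 2)
#' pu <- simulateReads(g, simConfig(100, 1, seed = 3))
#' ph <- callPseudohaploid(pu, seed = 4)
#' @export
callPseudohaploid <- function(pileup, seed) {
  r <- refCounts(pileup); a <- altCounts(pileup)
  d <- r + a
  call <- matrix(NA_integer_, nrow(d), ncol(d))
  withSeed(seed, {
    u <- matrix(runif(length(d)), nrow(d), ncol(d))
    covered <- d > 0
    call[covered] <- as.integer(u[covered] < a[covered] / d[covered])
  })
  PseudohaploidCalls(call, panel = new("SitePanel", rowRanges(pileup)),
                     individuals = colnames(pileup))
}

#' Per-read binomial-error genotype likelihoods
#'
#' For diploid genotype g (alt-allele count 0/1/2) the probability that a
#' read reports the alternative allele is `g/2 * (1 - e) + (1 - g/2) * e`,
#' where `e` is the per-read error rate. The likelihood of g given counts
#' (n_ref, n_alt) is the product over reads, and triples are normalised to
#' sum to one. Sites with zero depth are flagged missing (uninformative).
#'
#' @param pileup a `ReadPileup`.
#' @param error per-read error rate in \[0, 0.5).
#' @return A `GLMatrix` with assays `L0`, `L1`, `L2`.
#' @examples
#' # one alt read at error 0 gives the normalised triple (0, 1/3, 2/3)
#' @export
genotypeLikelihoods <- function(pileup, error = 0.001) {
  if (error < 0 || error >= 0.5)
    stop("error must lie in [0, 0.5)")
  r <- refCounts(pileup); a <- altCounts(pileup)
  e_alt <- c(error, 0.5, 1 - error)          # per-read alt prob for g = 0,1,2
  L <- lapply(1:3, function(gi) {
    # log-likelihood to stay finite at high depth; 0 reads contribute 0 even
    # when the per-read log-probability is -Inf (error = 0)
    la <- log(e_alt[gi]); lr <- log1p(-e_alt[gi])
    ta <- a * la
    if (is.infinite(la)) ta[a == 0] <- 0
    tr <- r * lr
    if (is.infinite(lr)) tr[r == 0] <- 0
    ta + tr
  })
  mx <- pmax(L[[1]], L[[2]], L[[3]])
  L <- lapply(L, function(x) exp(x - mx))
  s <- L[[1]] + L[[2]] + L[[3]]
  L <- lapply(L, function(x) x / s)
  miss <- (r + a) == 0
  for (i in 1:3) L[[i]][miss] <- NA_real_
  GLMatrix(L0 = L[[1]], L1 = L[[2]], L2 = L[[3]],
           panel = new("SitePanel", rowRanges(pileup)),
           individuals = colnames(pileup))
}
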