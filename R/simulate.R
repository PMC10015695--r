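#' Simulation configuration
#'
#' Bundles and validates the parameters of the read simulator. `mean_coverage`
#' is the Poisson mean per-site fold coverage (lambda); `base_error` the
#' per-read probability of reporting the other allele (sequencing error,
#' epsilon, at most 0.1); `deamination_rate` an additional per-read
#' ref-to-alt flip probability applied at C/T- and G/A-type sites only
#' (delta, at most 0.3), a strand-agnostic scalar stand-in for terminal
#' deamination damage. A seed is mandatory: every simulation is
#' bit-reproducible given its inputs and seed.
#'
#' @param n_sites number of panel sites.
#' @param mean_coverage Poisson mean fold coverage per site (>= 0).
#' @param base_error per-read error rate in \[0, 0.1\].
#' @param deamination_rate extra ref->alt flip rate in \[0, 0.3\] at
#'   deamination-prone sites.
#' @param freq_sampler allele-frequency sampler for [simulatePanel()].
#' @param seed integer root seed.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- simConfig(n_sites = 1000, mean_coverage = 2, seed = 1)
#' @export
simConfig <- function(n_sites, mean_coverage, base_error = 0.001,
                      deamination_rate = 0,
                      freq_sampler = function(n) runif(n, 0.05, 0.95),
                      seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_sites >= 1, mean_coverage >= 0)
  if (base_error < 0 || base_error > 0.1)
    stop("base_error must lie in [0, 0.1]")
  if (deamination_rate < 0 || deamination_rate > 0.3)
    stop("deamination_rate must lie in [0, 0.3]")
  structure(list(n_sites = as.integer(n_sites),
                 mean_coverage = mean_coverage, base_error = base_error,
                 deamination_rate = deamination_rate,
                 freq_sampler = freq_sampler, seed = as.integer(seed)),
            class = "sim_config")
}

#' Mendelian forward simulation of genotypes on a pedigree
#'
#' Founders draw two alleles independently as alternative with probability
#' `alt_freq` (Hardy--Weinberg equilibrium); each non-founder receives one
#' uniformly chosen allele from each parent, per site, independently.
#' Individuals flagged as duplicates receive a bitwise copy of their
#' original's genome.
#'
#' @param panel a [SitePanel-class].
#' @param ped a [Pedigree-class].
#' @param seed integer seed.
#' @return A [kinlow-containers] `GenotypeMatrix` (sites x individuals,
#'   values 0/1/2).
#' @examples
#' panel <- simulatePanel(200, seed = 1)
#' g <- simulateGenotypes(panel, pedigreeTrios(), seed = 2)
#' @export
simulateGenotypes <- function(panel, ped, seed) {
  validObject(ped)
  n <- length(panel)
  p <- altFreq(panel)
  ids <- ped@id
  ord <- topoOrder(ped)
  H1 <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  H2 <- H1
  withSeed(seed, {
    for (id in ord) {
      i <- match(id, ids)
      dup <- ped@duplicate_of[i]
      if (!is.na(dup)) {
        H1[, i] <- H1[, dup]
        H2[, i] <- H2[, dup]
      } else if (is.na(ped@mother[i])) {
        H1[, i] <- rbinom(n, 1L, p)
        H2[, i] <- rbinom(n, 1L, p)
      } else {
        m <- ped@mother[i]; f <- ped@father[i]
        pick_m <- rbinom(n, 1L, 0.5) == 1L
        pick_f <- rbinom(n, 1L, 0.5) == 1L
        H1[, i] <- ifelse(pick_m, H1[, m], H2[, m])
        H2[, i] <- ifelse(pick_f, H1[, f], H2[, f])
      }
    }
  })
  GenotypeMatrix(H1 + H2, panel, ids)
}

#' Simulate read pileups over a panel
#'
#' Per site and individual, read depth is Poisson with mean
#' `config$mean_coverage`; each read copies one of the two alleles uniformly
#' and flips to the other with probability `base_error`; at sites whose
#' ref/alt pairing is C/T or G/A (either orientation), each read additionally
#' flips ref->alt with probability `deamination_rate`.
#'
#' @param geno a `GenotypeMatrix`.
#' @param config a [simConfig()] object (its `seed` drives this step).
#' @return A `ReadPileup`.
#' @export
simulateReads <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  g <- genotypes(geno)
  n <- nrow(g); k <- ncol(g)
  panel <- rowRanges(geno)
  eps <- config$base_error
  p_alt <- g / 2 * (1 - eps) + (1 - g / 2) * eps
  if (config$deamination_rate > 0) {
    prone <- deaminationProne(panel)
    d <- config$deamination_rate
    p_alt[prone, ] <- p_alt[prone, ] + (1 - p_alt[prone, ]) * d
  }
  withSeed(config$seed, {
    depth <- matrix(rpois(n * k, config$mean_coverage), n, k)
    n_alt <- matrix(rbinom(n * k, as.vector(depth), as.vector(p_alt)), n, k)
  })
  ReadPileup(ref = depth - n_alt, alt = n_alt,
             panel = new("SitePanel", panel), individuals = colnames(g))
}

#' Binomial read thinning
#'
#' Retains each read independently with probability `fraction`, emulating
#' the downsampling of a sequencing library to 1--50% of its reads. Thinning
#' is unbiased: expected coverage scales by exactly `fraction`.
#'
#' @param pileup a `ReadPileup`.
#' @param fraction retention probability in \[0, 1\].
#' @param seed integer seed.
#' @return A thinned `ReadPileup` on the same panel and individuals.
#' @examples
#' panel <- simulatePanel(100, seed = 1)
#' g <- simulateGenotypes(panel, pedigreeUnrelated(2), seed = 2)
#' pu <- simulateReads(g, simConfig(100, 2, seed = 3))
#' half <- downsampleReads(pu, 0.5, seed = 4)
#' @export
downsampleReads <- function(pileup, fraction, seed) {
  if (length(fraction) != 1 || is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  r <- refCounts(pileup); a <- altCounts(pileup)
  if (fraction == 1) return(pileup)
  withSeed(seed, {
    r2 <- matrix(rbinom(length(r), as.vector(r), fraction), nrow(r), ncol(r))
    a2 <- matrix(rbinom(length(a), as.vector(a), fraction), nrow(a), ncol(a))
  })
  ReadPileup(ref = r2, alt = a2, panel = new("SitePanel", rowRanges(pileup)),
             individuals = colnames(pileup))
}

#' Mean fold coverage over panel sites
#'
#' Coverage is defined over the panel: total reads divided by the number of
#' panel sites, per individual. Use [roundCoverage()] for two-decimal report
#' formatting.
#'
#' @param pileup a `ReadPileup` with at least one site.
#' @return Named numeric vector, one mean coverage per individual.
#' @examples
#' # a single site with reads (3 ref, 1 alt) has coverage 4
#' @export
meanCoverage <- function(pileup) {
  if (nrow(pileup) == 0) stop("empty pileup")
  colSums(refCounts(pileup) + altCounts(pileup)) / nrow(pileup)
}
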