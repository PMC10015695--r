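# Shared simulation helpers. Heavier cohorts are built once per test run and
# cached, so several test files can reuse them.

simCohort <- function(ped, n_sites, coverage, error = 0, seed, deam = 0) {
  panel <- simulatePanel(n_sites, seed = subSeed(seed, "panel"))
  geno <- simulateGenotypes(panel, ped, seed = subSeed(seed, "geno"))
  pileup <- simulateReads(
    geno, simConfig(n_sites, coverage, error, deam, seed = subSeed(seed, "reads")))
  list(panel = panel, geno = geno, pileup = pileup)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# extended family (identical/1st/2nd/3rd/unrelated pairs), 50k sites, deep
# error-free reads + pseudohaploid calls: the closed-form limit cohort
familyDeep <- function() cached("familyDeep", function() {
  co <- simCohort(pedigreeFamily(), 50000, 10, error = 0, seed = 401)
  co$ph <- callPseudohaploid(co$pileup, seed = subSeed(401, "ph"))
  co
})

# parent-offspring pair inside an otherwise unrelated cohort of 11
poCohortDeep <- function() cached("poCohortDeep", function() {
  ped <- Pedigree(c(sprintf("u%d", 1:8), "mo", "fa", "ch"),
                  mother = c(rep(NA, 10), "mo"),
                  father = c(rep(NA, 10), "fa"))
  co <- simCohort(ped, 50000, 10, error = 0, seed = 402)
  co$ph <- callPseudohaploid(co$pileup, seed = subSeed(402, "ph"))
  co
})

# duplicated genome inside an otherwise unrelated cohort of 12
dupCohortDeep <- function() cached("dupCohortDeep", function() {
  ped <- Pedigree(c(sprintf("u%d", 1:10), "a", "a2"),
                  duplicate_of = c(rep(NA, 11), "a"))
  co <- simCohort(ped, 50000, 10, error = 0, seed = 403)
  co$ph <- callPseudohaploid(co$pileup, seed = subSeed(403, "ph"))
  co
})

# small deep-GL cohort: trio + two unrelated, 20k sites, 5x
glCohort <- function() cached("glCohort", function() {
  ped <- Pedigree(c("mo", "fa", "ch", "u1", "u2"),
                  mother = c(NA, NA, "mo", NA, NA),
                  father = c(NA, NA, "fa", NA, NA))
  co <- simCohort(ped, 20000, 5, error = 0.001, seed = 404)
  co$gl <- genotypeLikelihoods(co$pileup, 0.001)
  co
})

# same pedigree at depth 30: effectively known genotypes
deepGLCohort <- function() cached("deepGLCohort", function() {
  ped <- Pedigree(c("mo", "fa", "ch", "u1", "u2"),
                  mother = c(NA, NA, "mo", NA, NA),
                  father = c(NA, NA, "fa", NA, NA))
  co <- simCohort(ped, 10000, 30, error = 0.001, seed = 405)
  co$gl <- genotypeLikelihoods(co$pileup, 0.001)
  co
})

# independent per-site enumeration of the expected pseudohaploid mismatch
# probability given true genotypes: P(draw_i != draw_j) at each site
phMismatchOracle <- function(gi, gj) {
  (gi / 2) * (1 - gj / 2) + (1 - gi / 2) * (gj / 2)
}

# brute-force simplex grid maximiser for the IBD-coefficient likelihood,
# built from ibdJointTables site by site (independent of the EM path)
gridOracle <- function(Li, Lj, p, step = 0.01) {
  n <- nrow(Li)
  A <- matrix(0, n, 3)
  for (s in seq_len(n)) {
    tt <- ibdJointTables(p[s])
    outerL <- outer(Li[s, ], Lj[s, ])
    A[s, ] <- c(sum(outerL * tt$T0), sum(outerL * tt$T1), sum(outerL * tt$T2))
  }
  ks <- expand.grid(k0 = seq(0, 1, step), k1 = seq(0, 1, step))
  ks$k2 <- 1 - ks$k0 - ks$k1
  ks <- ks[ks$k2 >= -1e-12, ]
  K <- as.matrix(ks)
  K[K < 0] <- 0
  ll <- colSums(log(pmax(A %*% t(K), 1e-300)))
  i <- which.max(ll)
  list(k = unname(K[i, ]), phi = unname(K[i, 2] / 4 + K[i, 3] / 2),
       loglik = ll[i])
}

totalReads <- function(pu) sum(refCounts(pu)) + sum(altCounts(pu))

# one-site pileup for arithmetic checks
tinyPileup <- function(n_ref, n_alt) {
  panel <- SitePanel("s1", 1, 100, "A", "G", 0.5)
  ReadPileup(matrix(as.integer(n_ref)), matrix(as.integer(n_alt)),
             panel, "i1")
}
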