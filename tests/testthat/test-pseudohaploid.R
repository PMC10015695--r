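# hand-built call matrices on a fresh panel
handCalls <- function(panel, ...) {
  cols <- list(...)
  PseudohaploidCalls(do.call(cbind, cols), panel, names(cols))
}

test_that("windowed P0 is 0 for identical and 1 for complementary calls", {
  panel <- simulatePanel(4000, seed = 91)
  base <- withr::with_seed(92, sample(0:1, 4000, replace = TRUE))
  ph <- handCalls(panel, a = base, b = base, c = 1L - base)
  wp <- windowP0(ph)
  expect_true(all(wp$p0[wp$pair == "a|b"] == 0))
  expect_true(all(wp$p0[wp$pair == "a|c"] == 1))
  expect_true(all(wp$n_shared >= 1))
  # windows with no shared sites are omitted
  gap <- base
  gap[as.character(GenomicRanges::seqnames(panel)) == "1"] <- NA_integer_
  ph2 <- handCalls(panel, a = base, b = gap, c = 1L - base)
  wp2 <- windowP0(ph2)
  expect_false(any(wp2$chrom[wp2$pair == "a|b"] == "1"))
  expect_error(windowP0(handCalls(panel, a = base)), "two individuals")
})

test_that("per-site mismatch matches enumeration oracle and closed form", {
  co <- familyDeep()
  C <- phCalls(co$ph)
  G <- genotypes(co$geno)
  p <- altFreq(co$panel); q <- 1 - p
  mm <- kennettMismatch(co$ph)
  cases <- list(c("M", "N", 0), c("A", "G", 0.125), c("A", "C", 0.25),
                c("G", "L", 0.5))
  for (cs in cases) {
    i <- cs[1]; j <- cs[2]; phi <- as.numeric(cs[3])
    sh <- !is.na(C[, i]) & !is.na(C[, j])
    n <- sum(sh)
    m_emp <- mm$m[i, j]
    # oracle 1: enumeration of the draw probabilities given true genotypes
    P <- phMismatchOracle(G[sh, i], G[sh, j])
    expect_lt(abs(m_emp - mean(P)), 3 * sqrt(sum(P * (1 - P))) / n,
              label = sprintf("draw oracle, phi=%.3f", phi))
    # oracle 2: closed form E[mismatch] = 2 (1 - phi) p q
    E <- 2 * (1 - phi) * p[sh] * q[sh]
    expect_lt(abs(m_emp - mean(E)), 3 * sqrt(sum(E * (1 - E))) / n,
              label = sprintf("closed form, phi=%.3f", phi))
  }
})

test_that("cohort-normalised P0 recovers 1 - phi and classifies degrees", {
  # all-unrelated cohort: normalisation identity, nobody related
  un <- dupCohortDeep()$ph[, sprintf("u%d", 1:10)]
  rc0 <- readClassify(windowP0(un))
  expect_true(all(abs(rc0$normalized_p0 - 1) < 0.02))
  expect_false(any(rc0$related))

  # parent-offspring inside an unrelated cohort
  rc1 <- readClassify(windowP0(poCohortDeep()$ph))
  po <- rc1[rc1$pair %in% c("ch|mo", "ch|fa"), ]
  expect_true(all(abs(po$normalized_p0 - 0.75) < 0.02))
  expect_true(all(po$degree == "first"))
  expect_true(all(po$related))
  expect_false(any(rc1$related[!rc1$pair %in% c("ch|mo", "ch|fa")]))

  # duplicated genome
  rc2 <- readClassify(windowP0(dupCohortDeep()$ph))
  dup <- rc2[rc2$pair == "a|a2", ]
  expect_lt(abs(dup$normalized_p0 - 0.5), 0.02)
  expect_identical(dup$degree, "identical")

  # too few windows per pair -> flagged, not an exception
  thin <- downsampleReads(familyDeep()$pileup, 0.0008, seed = 93)
  rc3 <- readClassify(windowP0(callPseudohaploid(thin, seed = 94)))
  expect_true(all(rc3$flag == "insufficient"))
  expect_false(any(rc3$related))
})

test_that("mismatch-rate screen separates related from unrelated cohorts", {
  panel <- simulatePanel(2000, seed = 95)
  base <- withr::with_seed(96, sample(0:1, 2000, replace = TRUE))
  ph <- handCalls(panel, a = base, b = base, c = 1L - base)
  mm <- kennettMismatch(ph)
  expect_identical(mm$m["a", "b"], 0)
  expect_identical(mm$m["a", "c"], 1)
  expect_identical(mm$n_shared["a", "b"], 2000)

  # two individuals only: a single pair cannot support the screen
  expect_error(kennettScreen(kennettMismatch(ph[, c("a", "b")])), "3 pairs")

  un <- dupCohortDeep()$ph[, sprintf("u%d", 1:10)]
  expect_false(kennettScreen(kennettMismatch(un))$any_relatives)
  expect_true(kennettScreen(kennettMismatch(poCohortDeep()$ph))$any_relatives)
})

test_that("max-rate normalisation recovers r = 2 phi; screen suppresses nulls", {
  mm_po <- kennettMismatch(poCohortDeep()$ph)
  kr <- kennettR(mm_po)
  expect_lt(abs(kr$r[kr$pair == "ch|mo"] - 0.5), 0.04)
  expect_identical(kr$degree[kr$pair == "ch|mo"], "first")
  # the pair attaining the maximum rate has r = 0 by construction
  expect_identical(min(kr$r), 0)
  expect_identical(kr$degree[which.min(kr$r)], "unrelated")

  kr_dup <- kennettR(kennettMismatch(dupCohortDeep()$ph))
  expect_lt(abs(kr_dup$r[kr_dup$pair == "a|a2"] - 1.0), 0.04)

  # all-unrelated cohort: screen on -> nothing related; off -> r noise can
  # cross the second-degree boundary
  un <- dupCohortDeep()$ph[, sprintf("u%d", 1:10)]
  mm_un <- kennettMismatch(un)
  expect_false(any(kennettR(mm_un, apply_screen = TRUE)$related))

  # degenerate all-identical cohort
  panel <- simulatePanel(1000, seed = 97)
  same <- rep(1L, 1000)
  expect_error(kennettR(kennettMismatch(
    handCalls(panel, a = same, b = same, c = same))), "degenerate")
})

test_that("HRC recovers phi and reacts to mis-calibrated frequencies", {
  co <- poCohortDeep()
  h <- hrcEstimate(co$ph)
  u <- altFreq(co$panel)^2 + (1 - altFreq(co$panel))^2
  se_null <- sqrt(sum(u * (1 - u))) / sum(1 - u)
  expect_lt(abs(h$hrc[h$pair == "u1|u2"]), 3 * se_null)
  unrel <- h[!h$pair %in% c("ch|mo", "ch|fa", "fa|mo"), ]
  # max over 45 null pairs: 4.5 sigma keeps the family-wise rate ~3e-4
  expect_lt(max(abs(unrel$hrc)), 4.5 * se_null)
  expect_lt(abs(h$hrc[h$pair == "ch|mo"] - 0.25), 0.03)
  expect_true(h$related[h$pair == "ch|mo"])

  dup <- hrcEstimate(dupCohortDeep()$ph)
  expect_lt(abs(dup$hrc[dup$pair == "a|a2"] - 0.5), 0.03)

  # frequencies from the wrong population inflate unrelated pairs
  mis <- withr::with_seed(98, runif(length(co$panel), 0.3, 0.7))
  h_mis <- hrcEstimate(co$ph, freqs = mis)
  expect_gt(min(h_mis$hrc[!h_mis$pair %in% c("ch|mo", "ch|fa")]), 0.15)

  expect_error(hrcEstimate(co$ph, freqs = rep(1, length(co$panel))),
               "strictly inside")
  # insufficiency floor
  few <- hrcEstimate(co$ph, min_sites = 1e6)
  expect_true(all(few$flag == "insufficient"))
  expect_false(any(few$related))
})

test_that("all three estimators are invariant to consistent ref/alt relabel", {
  co <- familyDeep()
  C <- phCalls(co$ph)
  flip <- withr::with_seed(99, sample(c(TRUE, FALSE), nrow(C), replace = TRUE))
  C2 <- C
  C2[flip, ] <- 1L - C2[flip, ]
  f2 <- altFreq(co$panel)
  f2[flip] <- 1 - f2[flip]
  ph2 <- PseudohaploidCalls(C2, co$panel, colnames(C))
  expect_equal(readClassify(windowP0(ph2)), readClassify(windowP0(co$ph)))
  expect_equal(kennettMismatch(ph2)$m, kennettMismatch(co$ph)$m)
  expect_equal(hrcEstimate(ph2, freqs = f2)$hrc,
               hrcEstimate(co$ph)$hrc)
})

test_that("estimator variance grows as coverage falls", {
  ped <- Pedigree(c("mo", "fa", "ch", "u1", "u2", "u3"),
                  mother = c(NA, NA, "mo", NA, NA, NA),
                  father = c(NA, NA, "fa", NA, NA, NA))
  grid <- c(4, 0.5, 0.1)
  stat <- array(NA_real_, c(100, length(grid), 2))
  for (r in 1:100) {
    panel <- simulatePanel(4000, seed = subSeed(500, "p", r))
    geno <- simulateGenotypes(panel, ped, seed = subSeed(500, "g", r))
    for (ci in seq_along(grid)) {
      pu <- simulateReads(geno, simConfig(4000, grid[ci], 0,
                                          seed = subSeed(500, "r", r, ci)))
      ph <- callPseudohaploid(pu, seed = subSeed(500, "c", r, ci))
      mm <- kennettMismatch(ph)
      stat[r, ci, 1] <- mm$m["ch", "mo"]
      h <- hrcEstimate(ph, min_sites = 1)
      stat[r, ci, 2] <- h$hrc[h$pair == "ch|mo"]
    }
  }
  for (k in 1:2) {
    v <- apply(stat[, , k], 2, var, na.rm = TRUE)
    expect_true(all(diff(v) > 0),
                label = c("mismatch", "hrc")[k])
  }
})
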