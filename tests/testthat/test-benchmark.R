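test_that("relative kinship scores share the phi-derived scale", {
  expect_identical(relativeKinshipScore(1.0, "read"), 0)
  expect_identical(relativeKinshipScore(0.25, "lcmlkin"), 0.5)
  expect_identical(relativeKinshipScore(1.0, "kennett"), 1)
  expect_identical(relativeKinshipScore(0.5, "tkgwv2"), 1)
  expect_identical(relativeKinshipScore(0.25, "king"), 0.5)
  expect_error(relativeKinshipScore(1, "admixture"))
})

test_that("accuracy/consistency/FP/FN follow the set-arithmetic definitions", {
  mk <- function(pairs, related, fraction, flag = "ok")
    data.frame(method = "read", fraction = fraction, pair = pairs,
               stat = 1, score = 0, related = related,
               n_shared = 100, flag = flag, stringsAsFactors = FALSE)
  pairs <- sprintf("a|b%02d", 1:8)
  ref <- mk(pairs, c(rep(TRUE, 5), rep(FALSE, 3)), 1)
  # 4 of the 5 reference relationships plus 1 novel call
  red <- mk(pairs, c(rep(TRUE, 4), FALSE, TRUE, FALSE, FALSE), 0.5)
  ev <- evaluateCalls(rbind(ref, red))
  at <- ev[ev$fraction == 0.5, ]
  expect_equal(at$accuracy, 4 / 5)
  expect_equal(at$consistency, 4 / 5)
  expect_identical(at$fp, 1L)
  expect_identical(at$fn, 1L)
  # identity at full retention
  full <- ev[ev$fraction == 1, ]
  expect_identical(full$accuracy, 1)
  expect_identical(full$consistency, 1)
  expect_identical(full$fp + full$fn, 0L)

  # empty reduced-coverage call set: consistency 0, accuracy undefined
  none <- mk(pairs, rep(FALSE, 8), 0.1)
  ev2 <- evaluateCalls(rbind(ref, none))
  at2 <- ev2[ev2$fraction == 0.1, ]
  expect_identical(at2$consistency, 0)
  expect_true(is.na(at2$accuracy))
  expect_identical(at2$fn, 5L)

  # insufficient reference pairs drop out of the consistency denominator
  part <- mk(pairs, c(TRUE, TRUE, rep(FALSE, 6)), 0.25,
             flag = c(rep("ok", 4), rep("insufficient", 4)))
  ev3 <- evaluateCalls(rbind(ref, part))
  at3 <- ev3[ev3$fraction == 0.25, ]
  expect_equal(at3$consistency, 2 / 4)
  expect_identical(at3$fn, 3L)

  # truth-based counts
  ev4 <- evaluateCalls(rbind(ref, red), truth = pairs[1:4])
  at4 <- ev4[ev4$fraction == 0.5, ]
  expect_identical(at4$fp_truth, 1L)
  expect_identical(at4$fn_truth, 0L)
})

test_that("sweep input contracts are enforced", {
  co <- simCohort(pedigreeUnrelated(2), 500, 1, seed = 201)
  expect_error(runSweep(co$pileup, seed = 1), "3 individuals")
  co3 <- simCohort(pedigreeUnrelated(3), 500, 1, seed = 202)
  expect_error(runSweep(co3$pileup, methods = "plink", seed = 1), "unknown")
  expect_error(runSweep(co3$pileup, fractions = c(1, 0), seed = 1),
               "fractions")
  expect_error(runSweep(co3$pileup, methods = character(0), seed = 1),
               "non-empty")
})

test_that("sweep is deterministic and complete over pairs and fractions", {
  ped <- Pedigree(c("mo", "fa", "ch", "u1"),
                  mother = c(NA, NA, "mo", NA),
                  father = c(NA, NA, "fa", NA))
  co <- simCohort(ped, 6000, 2, error = 0.001, seed = 203)
  sw <- runSweep(co$pileup, methods = c("kennett", "tkgwv2", "king"),
                 fractions = c(1, 0.25), seed = 7, min_sites = 200)
  sw2 <- runSweep(co$pileup, methods = c("kennett", "tkgwv2", "king"),
                  fractions = c(1, 0.25), seed = 7, min_sites = 200)
  expect_identical(sw, sw2)
  expect_identical(nrow(sw$calls), 3L * 2L * 6L)
  expect_identical(sort(unique(sw$calls$fraction)), c(0.25, 1))
  expect_true(all(!sw$calls$related[sw$calls$flag != "ok"]))
  # parent-offspring found by every method at full retention
  po <- sw$calls[sw$calls$fraction == 1 & sw$calls$pair == "ch|mo", ]
  expect_true(all(po$related))
  # coverage table scales with the retention fraction
  cv <- sw$coverage
  full <- cv$coverage[cv$fraction == 1]
  quarter <- cv$coverage[cv$fraction == 0.25]
  expect_true(all(abs(quarter - 0.25 * full) < 0.1))
})

test_that("mantel matrices reproduce hand-computed toy distances", {
  calls <- data.frame(
    method = "tkgwv2", fraction = rep(c(1, 0.5), each = 3),
    pair = rep(c("a|b", "a|c", "b|c"), 2),
    stat = c(0.25, 0.125, 0, 0.2, 0.1, 0.05),
    score = c(0.5, 0.25, 0, 0.4, 0.2, 0.1),
    related = FALSE, n_shared = 1000, flag = "ok",
    stringsAsFactors = FALSE)
  coverage <- data.frame(
    individual = rep(c("a", "b", "c"), 2), fraction = rep(c(1, 0.5), each = 3),
    coverage = c(2, 1, 3, 1, 0.5, 1.5))
  m <- buildMantelMatrices(list(calls = calls, coverage = coverage), "tkgwv2")
  expect_identical(dim(m$score), c(6L, 6L))
  expect_equal(m$score["a|b@1", "a|c@1"], 0.25)
  expect_equal(m$score["a|b@1", "a|b@0.5"], 0.1)
  # pairwise mean coverages: a|b@1 -> 1.5, a|c@1 -> 2.5, a|b@0.5 -> 0.75
  expect_equal(m$coverage["a|b@1", "a|c@1"], 1)
  expect_equal(m$coverage["a|b@1", "a|b@0.5"], 0.75)
  expect_identical(unname(diag(m$score)), rep(0, 6))

  expect_error(buildMantelMatrices(
    list(calls = calls[1:3, ], coverage = coverage), "tkgwv2"), "at least 4")
})

test_that("mantel test: identity, validation, exact enumeration", {
  m <- as.matrix(dist(c(1, 3, 6, 10, 15)))
  self <- mantelTest(m, m, seed = 1)
  expect_identical(self$r, 1)
  expect_true(self$exact)
  expect_identical(self$n_perm, 120L)
  expect_true(self$p >= 1 / 120 && self$p <= 1)

  expect_error(mantelTest(m, m[1:4, 1:4], seed = 1), "same size")
  asym <- m; asym[1, 2] <- 99
  expect_error(mantelTest(asym, m, seed = 1), "symmetric")
  diag_bad <- m; diag(diag_bad) <- 1
  expect_error(mantelTest(diag_bad, m, seed = 1), "zero diagonal")
  expect_error(mantelTest(m[1:3, 1:3], m[1:3, 1:3], seed = 1), "at least 4")

  zero <- matrix(0, 5, 5)
  expect_true(mantelTest(m, zero, seed = 1)$degenerate)

  # monotone association across two coverage levels gives r > 0
  calls <- data.frame(
    method = "king", fraction = rep(c(1, 0.25), each = 3),
    pair = rep(c("a|b", "a|c", "b|c"), 2),
    stat = NA, score = c(0.50, 0.52, 0.48, 0.20, 0.22, 0.18),
    related = FALSE, n_shared = 1000, flag = "ok", stringsAsFactors = FALSE)
  coverage <- data.frame(
    individual = rep(c("a", "b", "c"), 2),
    fraction = rep(c(1, 0.25), each = 3), coverage = c(2, 2, 2, 0.5, 0.5, 0.5))
  mm <- buildMantelMatrices(list(calls = calls, coverage = coverage), "king")
  mt <- mantelTest(mm$score, mm$coverage, seed = 2)
  expect_gt(mt$r, 0)
})

test_that("mantel r agrees with the independent vegan implementation", {
  withr::with_seed(302, {
    a <- as.matrix(dist(rnorm(12)))
    b <- as.matrix(dist(rnorm(12)))
  })
  ours <- mantelTest(a, b, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic))
})

test_that("permutation p agrees with exact enumeration and is calibrated", {
  set.seed(301)
  a <- as.matrix(dist(rnorm(5)))
  b <- as.matrix(dist(rnorm(5)))
  ex <- mantelTest(a, b, seed = 1)
  pm <- mantelTest(a, b, n_perm = 9999, seed = 2, exact = FALSE)
  expect_true(ex$exact)
  expect_false(pm$exact)
  expect_lt(abs(ex$p - pm$p), 0.02)

  # null calibration: exact p over 500 independent replicates ~ uniform
  ps <- vapply(1:500, function(i) {
    withr::with_seed(1000 + i, {
      aa <- as.matrix(dist(rnorm(5)))
      bb <- as.matrix(dist(rnorm(5)))
    })
    mantelTest(aa, bb, seed = i)$p
  }, numeric(1))
  # exact p values sit on the 1/120 grid, so ks.test warns about ties
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("kennett screen suppresses spurious calls on unrelated cohorts", {
  # sparse regime (few shared sites): without the screen the max-rate
  # normalisation over-calls in most seeds; with it, never
  on_seeds <- off_seeds <- 0L
  for (s in 1:9) {
    co <- simCohort(pedigreeUnrelated(5), 2000, 1, error = 0.001,
                    seed = subSeed(205, s))
    ph <- callPseudohaploid(co$pileup, seed = subSeed(206, s))
    mm <- kennettMismatch(ph)
    sc <- kennettScreen(mm)
    on_seeds <- on_seeds +
      (sum(kennettR(mm, sc, apply_screen = TRUE)$related) > 0L)
    off_seeds <- off_seeds +
      (sum(kennettR(mm, sc, apply_screen = FALSE)$related) > 0L)
  }
  expect_identical(on_seeds, 0L)
  expect_gt(off_seeds, 4L)   # majority of seeds over-call without the screen
})
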