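SWEEP_METHODS <- c("read", "kennett", "tkgwv2", "lcmlkin", "king")
PH_METHODS <- c("read", "kennett", "tkgwv2")
GL_METHODS <- c("lcmlkin", "king")

#' Map an estimator statistic onto a common relative kinship scale
#'
#' Every method's raw statistic is mapped onto the kinship-coefficient
#' scale — `1 - normalized_p0` for the windowed-mismatch method, `r / 2`
#' for the max-rate-normalised coefficient, `hrc`, `phi` and `king`
#' directly — then divided by 0.5 so that an identical pair scores 1,
#' first degree 0.5, second degree 0.25 and unrelated 0. This common scale
#' makes kinship scores comparable across method families.
#'
#' @param stat numeric raw statistic(s).
#' @param method one of `"read"`, `"kennett"`, `"tkgwv2"`, `"lcmlkin"`,
#'   `"king"`.
#' @return Relative kinship score(s).
#' @examples
#' relativeKinshipScore(1.0, "read")     # 0: unrelated
#' relativeKinshipScore(0.25, "lcmlkin") # 0.5: first degree
#' @export
relativeKinshipScore <- function(stat, method) {
  method <- match.arg(method, SWEEP_METHODS)
  phi <- switch(method,
                read = 1 - stat,
                kennett = stat / 2,
                tkgwv2 = stat,
                lcmlkin = stat,
                king = stat)
  phi / 0.5
}

methodCalls <- function(method, ph, gl, freqs, min_sites, min_windows,
                        apply_screen, window_bp) {
  if (method == "read") {
    res <- readClassify(windowP0(ph, window_bp), min_windows = min_windows)
    data.frame(pair = res$pair, stat = res$normalized_p0,
               related = res$related, n_shared = res$n_windows,
               flag = res$flag, stringsAsFactors = FALSE)
  } else if (method == "kennett") {
    mm <- kennettMismatch(ph)
    res <- kennettR(mm, kennettScreen(mm), apply_screen = apply_screen)
    data.frame(pair = res$pair, stat = res$r, related = res$related,
               n_shared = res$n_shared, flag = res$flag,
               stringsAsFactors = FALSE)
  } else if (method == "tkgwv2") {
    res <- hrcEstimate(ph, freqs, min_sites = min_sites)
    data.frame(pair = res$pair, stat = res$hrc, related = res$related,
               n_shared = res$n_shared, flag = res$flag,
               stringsAsFactors = FALSE)
  } else if (method == "lcmlkin") {
    res <- pairwiseML(gl, freqs, min_sites = min_sites)
    data.frame(pair = res$pair, stat = res$phi, related = res$related,
               n_shared = res$n_sites, flag = res$flag,
               stringsAsFactors = FALSE)
  } else {
    res <- pairwiseKing(gl, freqs, min_sites = min_sites)
    data.frame(pair = res$pair, stat = res$king, related = res$related,
               n_shared = res$n_sites, flag = res$flag,
               stringsAsFactors = FALSE)
  }
}

#' Coverage-retention sweep over kinship methods
#'
#' For each retention fraction (1.0 being the original data), thins the
#' pileup by binomial sampling, regenerates pseudohaploid calls and
#' genotype likelihoods, runs every requested method, and records the
#' binary related call (second degree or closer) together with the raw
#' statistic and its relative kinship score. All randomness is derived from
#' `seed` through named sub-streams per (stage, fraction), so the sweep is
#' bit-reproducible.
#'
#' A method that fails on degenerate thinned data (e.g. no pair sharing a
#' site) contributes insufficient-flagged rows rather than aborting the
#' sweep.
#'
#' @param pileup a `ReadPileup` covering >= 3 individuals.
#' @param methods subset of `"read"`, `"kennett"`, `"tkgwv2"`, `"lcmlkin"`,
#'   `"king"`.
#' @param fractions retention fractions in (0, 1\]; 1.0 is the
#'   maximum-coverage reference level and is added if absent.
#' @param seed integer root seed.
#' @param gl_error per-read error rate for the likelihood model.
#' @param freqs population allele frequencies (default: the panel's).
#' @param min_sites,min_windows insufficiency floors passed to the methods.
#' @param apply_screen honour the mismatch-rate significance screen of the
#'   max-rate-normalised method.
#' @param window_bp window span for the windowed-mismatch method.
#' @return A list: `calls` (data.frame with `method`, `fraction`, `pair`,
#'   `stat`, `score`, `related`, `n_shared`, `flag`) and `coverage`
#'   (data.frame with `individual`, `fraction`, `coverage`).
#' @export
runSweep <- function(pileup, methods = SWEEP_METHODS,
                     fractions = c(1, 0.5, 0.25, 0.1, 0.05, 0.01), seed,
                     gl_error = 0.001, freqs = altFreq(pileup),
                     min_sites = 500, min_windows = 10,
                     apply_screen = TRUE, window_bp = 1e6) {
  if (ncol(pileup) < 3) stop("sweep needs at least 3 individuals")
  if (length(methods) == 0) stop("methods must be non-empty")
  bad <- setdiff(methods, SWEEP_METHODS)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  fractions <- sort(unique(c(1, fractions)), decreasing = TRUE)
  ids <- colnames(pileup)
  prs <- allPairs(ids)
  all_keys <- pairKey(prs[, 1], prs[, 2])
  calls <- list(); covg <- list()
  for (f in fractions) {
    thinned <- if (f == 1) pileup
               else downsampleReads(pileup, f, subSeed(seed, "thin", f))
    cv <- meanCoverage(thinned)
    covg[[length(covg) + 1]] <-
      data.frame(individual = names(cv), fraction = f, coverage = unname(cv))
    ph <- if (any(methods %in% PH_METHODS))
      callPseudohaploid(thinned, subSeed(seed, "phcall", f)) else NULL
    gl <- if (any(methods %in% GL_METHODS))
      genotypeLikelihoods(thinned, gl_error) else NULL
    for (method in methods) {
      res <- tryCatch(
        methodCalls(method, ph, gl, freqs, min_sites, min_windows,
                    apply_screen, window_bp),
        error = function(e)
          data.frame(pair = all_keys, stat = NA_real_, related = FALSE,
                     n_shared = 0, flag = "insufficient",
                     stringsAsFactors = FALSE))
      # every pair appears at every (method, fraction)
      missing_pairs <- setdiff(all_keys, res$pair)
      if (length(missing_pairs))
        res <- rbind(res, data.frame(pair = missing_pairs, stat = NA_real_,
                                     related = FALSE, n_shared = 0,
                                     flag = "insufficient",
                                     stringsAsFactors = FALSE))
      res$score <- relativeKinshipScore(res$stat, method)
      res$method <- method
      res$fraction <- f
      calls[[length(calls) + 1]] <-
        res[, c("method", "fraction", "pair", "stat", "score", "related",
                "n_shared", "flag")]
    }
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       coverage = do.call(rbind, covg))
}

#' Accuracy, consistency and error counts against the max-coverage reference
#'
#' For each method, the related pairs called at full retention form the
#' reference set. At each reduced fraction:
#'
#' * accuracy = consistent calls / calls at that fraction,
#' * consistency = consistent calls / reference calls (reference pairs that
#'   are insufficient at the reduced fraction are excluded from numerator
#'   and denominator),
#' * false positives = calls at the fraction not in the reference,
#' * false negatives = reference calls not made at the fraction
#'   (an insufficient pair makes no call, so it can count here).
#'
#' When a pedigree truth is supplied, `fp_truth`/`fn_truth` are also
#' reported against the true related set.
#'
#' @param sweep output of [runSweep()] (or its `calls` data.frame).
#' @param truth optional character vector of truly related pair keys (e.g.
#'   `truthTable(ped)$pair[truthTable(ped)$related]`).
#' @return A data.frame per (method, fraction): `n_identified`, `accuracy`,
#'   `consistency`, `fp`, `fn`, and `fp_truth`/`fn_truth` when truth given.
#' @export
evaluateCalls <- function(sweep, truth = NULL) {
  calls <- if (is.data.frame(sweep)) sweep else sweep$calls
  out <- list()
  for (method in unique(calls$method)) {
    d <- calls[calls$method == method, ]
    if (!any(d$fraction == 1))
      stop("reference calls at fraction 1 are required")
    ref <- d$pair[d$fraction == 1 & d$related]
    for (f in sort(unique(d$fraction), decreasing = TRUE)) {
      df <- d[d$fraction == f, ]
      called <- df$pair[df$related]
      ok_pairs <- df$pair[df$flag == "ok"]
      ref_eval <- intersect(ref, ok_pairs)
      consistent <- intersect(called, ref)
      row <- data.frame(
        method = method, fraction = f, n_identified = length(called),
        accuracy = if (length(called)) length(consistent) / length(called)
                   else NA_real_,
        consistency = if (length(ref_eval))
          length(intersect(called, ref_eval)) / length(ref_eval)
          else NA_real_,
        fp = length(setdiff(called, ref)),
        fn = length(setdiff(ref, called)),
        stringsAsFactors = FALSE)
      if (!is.null(truth)) {
        row$fp_truth <- length(setdiff(called, truth))
        row$fn_truth <- length(setdiff(truth, called))
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Distance matrices for the score-vs-coverage Mantel test
#'
#' Observation units are (pair, fraction) tuples of one method with an
#' ok flag and a defined relative kinship score. The first matrix holds
#' absolute differences of relative kinship scores; the second absolute
#' differences of pairwise mean coverage, where a tuple's coverage is the
#' mean of its two individuals' mean panel coverage at that fraction.
#'
#' @param sweep output of [runSweep()].
#' @param method the single method to extract.
#' @return A list of two symmetric zero-diagonal matrices, `score` and
#'   `coverage`, with at least 4 observations.
#' @export
buildMantelMatrices <- function(sweep, method) {
  calls <- sweep$calls
  d <- calls[calls$method == method & calls$flag == "ok" &
               !is.na(calls$score), ]
  if (nrow(d) < 4) stop("need at least 4 usable (pair, fraction) observations")
  cv <- sweep$coverage
  idm <- do.call(rbind, strsplit(d$pair, "|", fixed = TRUE))
  cov_of <- function(ind, f)
    cv$coverage[match(paste(ind, f), paste(cv$individual, cv$fraction))]
  pair_cov <- (cov_of(idm[, 1], d$fraction) + cov_of(idm[, 2], d$fraction)) / 2
  lab <- paste(d$pair, d$fraction, sep = "@")
  score_m <- abs(outer(d$score, d$score, "-"))
  cov_m <- abs(outer(pair_cov, pair_cov, "-"))
  dimnames(score_m) <- dimnames(cov_m) <- list(lab, lab)
  list(score = score_m, coverage = cov_m)
}
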