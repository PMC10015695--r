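#' Windowed pairwise mismatch proportions (P0)
#'
#' Divides each chromosome into fixed windows (default 1 Mbp, half-open
#' `[start, start + window_bp)`) and, for every unordered pair of
#' individuals, computes within each window the proportion of shared
#' non-missing pseudohaploid calls that differ (P0). Windows with no shared
#' sites for a pair are omitted.
#'
#' @param ph a `PseudohaploidCalls` object with >= 2 individuals.
#' @param window_bp window span in bp (default 1e6).
#' @return A data.frame with columns `pair`, `chrom`, `win_start`, `p0`,
#'   `n_shared`.
#' @export
windowP0 <- function(ph, window_bp = 1e6) {
  C <- phCalls(ph)
  if (ncol(C) < 2) stop("need at least two individuals")
  panel <- rowRanges(ph)
  chrom <- as.character(seqnames(panel))
  wstart <- floor((start(panel) - 1) / window_bp) * window_bp + 1
  wf <- factor(paste(chrom, wstart, sep = "@"))
  wmeta <- do.call(rbind, strsplit(levels(wf), "@", fixed = TRUE))
  prs <- allPairs(colnames(C))
  out <- vector("list", nrow(prs))
  for (k in seq_len(nrow(prs))) {
    ci <- C[, prs[k, 1]]; cj <- C[, prs[k, 2]]
    sh <- !is.na(ci) & !is.na(cj)
    n_sh <- as.vector(rowsum(as.numeric(sh), wf))
    n_mm <- as.vector(rowsum(as.numeric(sh & ci != cj), wf))
    keep <- n_sh >= 1
    if (!any(keep)) next
    out[[k]] <- data.frame(pair = pairKey(prs[k, 1], prs[k, 2]),
                           chrom = wmeta[keep, 1],
                           win_start = as.numeric(wmeta[keep, 2]),
                           p0 = n_mm[keep] / n_sh[keep],
                           n_shared = n_sh[keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cohort-normalised window-mismatch classification
#'
#' The mean P0 of each pair is normalised by the cohort mean of all pairs'
#' mean P0 — the expected mismatch level of an unrelated pair when most of
#' the cohort is unrelated — giving a statistic with expectation `1 - phi`
#' (1 for unrelated pairs, 0.75 first degree, 0.875 second, 0.5 identical).
#' Degrees are assigned by nearest expectation with midpoint boundaries, and
#' a pair is called related (second degree or closer) only when its
#' normalised P0 also differs significantly from 1 by a delete-one-window
#' jackknife z test.
#'
#' @param wp0 output of [windowP0()].
#' @param min_windows minimum windows per pair (default 10); pairs below it
#'   are flagged `insufficient` and never called related.
#' @param z_crit significance gate on `z = (1 - normalized_p0) / se`
#'   (default 1.96).
#' @return A data.frame per pair: `pair`, `mean_p0`, `normalized_p0`, `se`,
#'   `n_windows`, `z_unrelated`, `degree`, `related`, `flag`.
#' @export
readClassify <- function(wp0, min_windows = 10, z_crit = 1.96) {
  sp <- split(wp0, wp0$pair)
  if (length(sp) < 3) stop("cohort normalisation needs at least 3 pairs")
  mean_p0 <- vapply(sp, function(d) mean(d$p0), numeric(1))
  n_win <- vapply(sp, nrow, integer(1))
  se_mean <- vapply(sp, function(d) jackknifeSE(d$p0), numeric(1))
  ok <- n_win >= min_windows
  cohort <- if (any(ok)) mean(mean_p0[ok]) else mean(mean_p0)
  norm <- mean_p0 / cohort
  se <- se_mean / cohort
  z <- (1 - norm) / se
  expected <- c(unrelated = 1.0, second = 0.875, first = 0.75,
                identical = 0.5)
  degree <- classifyNearest(norm, expected)
  related <- ok & degree %in% c("identical", "first", "second") &
    !is.na(z) & z > z_crit
  data.frame(pair = names(sp), mean_p0 = unname(mean_p0),
             normalized_p0 = unname(norm), se = unname(se),
             n_windows = unname(n_win), z_unrelated = unname(z),
             degree = unname(degree), related = unname(related),
             flag = ifelse(ok, "ok", "insufficient"),
             row.names = NULL, stringsAsFactors = FALSE)
}
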