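# gzip-transparent connection helpers (base R's file() auto-detects gzip on
# read; writing uses gzfile when the path ends in .gz)
outConn <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Read and write site panels
#'
#' The panel is serialised as an EIGENSTRAT-style `.snp` file dialect
#' (whitespace-separated: site_id, chromosome, genetic position — ignored on
#' read and rewritten as 0.0 —, physical position, ref allele, alt allele)
#' plus a tab-separated frequency file (`site_id`, `alt_freq`). Reading
#' validates uniqueness of site ids, allele characters and strictly
#' increasing positions within a chromosome, reporting the offending line.
#'
#' @param panel a [SitePanel-class].
#' @param snp_path path of the `.snp` file.
#' @param freq_path path of the frequency TSV.
#' @return `readPanel` returns a [SitePanel-class]; `writePanel` the paths,
#'   invisibly. Round trip is exact.
#' @name panel-io
NULL

#' @rdname panel-io
#' @export
writePanel <- function(panel, snp_path, freq_path) {
  d <- data.frame(site_id = siteIDs(panel),
                  chrom = as.character(seqnames(panel)),
                  gpos = "0.0", pos = start(panel),
                  ref = refAllele(panel), alt = altAllele(panel))
  write.table(d, snp_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  f <- data.frame(site_id = siteIDs(panel),
                  alt_freq = format(altFreq(panel), digits = 15))
  con <- outConn(freq_path)
  writeLines("site_id\talt_freq", con)
  writeLines(paste(f$site_id, f$alt_freq, sep = "\t"), con)
  close(con)
  invisible(c(snp_path, freq_path))
}

#' @rdname panel-io
#' @export
readPanel <- function(snp_path, freq_path) {
  d <- read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("site_id", "chrom", "gpos", "pos",
                                "ref", "alt"),
                  colClasses = c("character", "character", "character",
                                 "integer", "character", "character"))
  dup <- which(duplicated(d$site_id))
  if (length(dup))
    stop("duplicate site_id at line ", dup[1], ": ", d$site_id[dup[1]])
  for (ch in unique(d$chrom)) {
    i <- which(d$chrom == ch)
    bad <- i[c(FALSE, diff(d$pos[i]) <= 0)]
    if (length(bad))
      stop("non-increasing position at line ", bad[1],
           " (chromosome ", ch, ")")
  }
  badnt <- which(!(d$ref %in% c("A", "C", "G", "T")) |
                   !(d$alt %in% c("A", "C", "G", "T")) | d$ref == d$alt)
  if (length(badnt)) stop("bad allele characters at line ", badnt[1])
  f <- read.table(freq_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!all(c("site_id", "alt_freq") %in% names(f)))
    stop("frequency file must have columns site_id and alt_freq")
  m <- match(d$site_id, f$site_id)
  if (anyNA(m)) stop("missing frequency for site ", d$site_id[which(is.na(m))[1]])
  SitePanel(d$site_id, d$chrom, d$pos, d$ref, d$alt, f$alt_freq[m])
}

#' Read and write container TSVs
#'
#' Long-format, gzip-transparent TSV serialisations with headers:
#'
#' * pileup: `individual_id`, `site_id`, `n_ref`, `n_alt`;
#' * pseudohaploid calls: `individual_id`, `site_id`, `call` with call in
#'   \{0 ref, 1 alt, 9 missing\};
#' * genotype likelihoods: `individual_id`, `site_id`, `L0`, `L1`, `L2`
#'   (missing sites omitted; triples must sum to 1 within 1e-6).
#'
#' Readers validate the schema by column name, reject negative counts and
#' individual/site ids absent from the panel, and return the matching
#' container on the panel's full site set.
#'
#' @param x the container to write.
#' @param path TSV path (`.gz` for compressed).
#' @param panel the [SitePanel-class] the file refers to.
#' @return Readers return the container; writers the path, invisibly.
#' @name container-io
NULL

longWrite <- function(df, path) {
  con <- outConn(path)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  close(con)
  invisible(path)
}

readCheck <- function(d, path, need, panel) {
  if (!all(need %in% names(d)))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(!(d$site_id %in% siteIDs(panel)))
  if (length(bad))
    stop("site_id not in panel: ", d$site_id[bad[1]])
  invisible(TRUE)
}

#' @rdname container-io
#' @export
writePileup <- function(x, path) {
  r <- refCounts(x); a <- altCounts(x)
  df <- data.frame(
    individual_id = rep(colnames(x), each = nrow(x)),
    site_id = rep(siteIDs(x), ncol(x)),
    n_ref = as.vector(r), n_alt = as.vector(a))
  longWrite(df, path)
}

#' @rdname container-io
#' @export
readPileup <- function(path, panel) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  readCheck(d, path, c("individual_id", "site_id", "n_ref", "n_alt"), panel)
  if (any(d$n_ref < 0 | d$n_alt < 0)) stop("negative read counts in ", path)
  ids <- unique(d$individual_id)
  n <- length(panel)
  ref <- alt <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  ri <- match(d$site_id, siteIDs(panel))
  ci <- match(d$individual_id, ids)
  ref[cbind(ri, ci)] <- as.integer(d$n_ref)
  alt[cbind(ri, ci)] <- as.integer(d$n_alt)
  ReadPileup(ref, alt, panel, ids)
}

#' @rdname container-io
#' @export
writeCalls <- function(x, path) {
  cl <- phCalls(x)
  v <- as.vector(cl)
  v[is.na(v)] <- 9L
  df <- data.frame(individual_id = rep(colnames(x), each = nrow(x)),
                   site_id = rep(siteIDs(x), ncol(x)), call = v)
  longWrite(df, path)
}

#' @rdname container-io
#' @export
readCalls <- function(path, panel) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  readCheck(d, path, c("individual_id", "site_id", "call"), panel)
  if (!all(d$call %in% c(0L, 1L, 9L)))
    stop("calls must be 0, 1 or 9 in ", path)
  ids <- unique(d$individual_id)
  call <- matrix(NA_integer_, length(panel), length(ids),
                 dimnames = list(NULL, ids))
  v <- ifelse(d$call == 9L, NA_integer_, as.integer(d$call))
  call[cbind(match(d$site_id, siteIDs(panel)),
             match(d$individual_id, ids))] <- v
  PseudohaploidCalls(call, panel, ids)
}

#' @rdname container-io
#' @export
writeGLs <- function(x, path) {
  L <- likelihoods(x)
  keep <- !is.na(as.vector(L$L1))
  df <- data.frame(
    individual_id = rep(colnames(x), each = nrow(x))[keep],
    site_id = rep(siteIDs(x), ncol(x))[keep],
    L0 = signif(as.vector(L$L0)[keep], 6),
    L1 = signif(as.vector(L$L1)[keep], 6),
    L2 = signif(as.vector(L$L2)[keep], 6))
  longWrite(df, path)
}

#' @rdname container-io
#' @export
readGLs <- function(path, panel) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  readCheck(d, path, c("individual_id", "site_id", "L0", "L1", "L2"), panel)
  s <- d$L0 + d$L1 + d$L2
  if (any(abs(s - 1) > 1e-6))
    stop("likelihood triple not summing to 1 in ", path,
         " (first at data row ", which(abs(s - 1) > 1e-6)[1], ")")
  ids <- unique(d$individual_id)
  n <- length(panel)
  L0 <- L1 <- L2 <- matrix(NA_real_, n, length(ids),
                           dimnames = list(NULL, ids))
  idx <- cbind(match(d$site_id, siteIDs(panel)), match(d$individual_id, ids))
  # renormalise away 6-digit rounding so the validity tolerance holds
  L0[idx] <- d$L0 / s; L1[idx] <- d$L1 / s; L2[idx] <- d$L2 / s
  GLMatrix(L0, L1, L2, panel, ids)
}

#' Write a per-pair results table
#'
#' Writes any of the per-pair data.frames produced by the estimators (or
#' [runSweep()] calls) as a TSV with floats at 6 significant digits.
#'
#' @param df a data.frame.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeResults <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
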