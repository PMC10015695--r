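#' Construct a SitePanel
#'
#' @param site_id character vector of unique site identifiers.
#' @param chrom chromosome labels (small positive integers, autosomes).
#' @param pos 1-based physical positions (bp), strictly increasing within
#'   each chromosome.
#' @param ref,alt single-nucleotide reference and alternative alleles.
#' @param alt_freq population alternative-allele frequencies in (0, 1).
#' @return A [SitePanel-class] object.
#' @examples
#' SitePanel("rs1", 1, 1000, "A", "G", 0.3)
#' @export
SitePanel <- function(site_id, chrom, pos, ref, alt, alt_freq) {
  gr <- GRanges(seqnames = as.character(chrom),
                ranges = IRanges(start = as.integer(pos), width = 1L),
                site_id = as.character(site_id),
                ref = as.character(ref), alt = as.character(alt),
                alt_freq = as.numeric(alt_freq))
  new("SitePanel", gr)
}

#' Simulate a synthetic ascertained SNP panel
#'
#' Generates `n_sites` biallelic sites spread over the 22 autosomes at
#' regular spacing, with population alternative-allele frequencies drawn
#' from `freq_sampler`. The panel emulates, at reduced size, an ascertained
#' capture panel of sites known to be polymorphic (the "1240k" set), so that
#' window-based estimators see a predictable site density.
#'
#' @param n_sites number of sites (>= 1).
#' @param freq_sampler function of one argument `n` returning `n` allele
#'   frequencies in (0, 1); default uniform on \[0.05, 0.95\].
#' @param seed integer seed (mandatory; the panel is deterministic given it).
#' @param spacing_bp distance between consecutive sites on a chromosome
#'   (default 2500 bp, giving 400 sites per 1 Mbp window).
#' @return A [SitePanel-class].
#' @examples
#' p <- simulatePanel(1000, seed = 1)
#' head(altFreq(p))
#' @export
simulatePanel <- function(n_sites,
                          freq_sampler = function(n) runif(n, 0.05, 0.95),
                          seed, spacing_bp = 2500L) {
  if (length(n_sites) != 1 || is.na(n_sites) || n_sites < 1)
    stop("n_sites must be a positive integer")
  n_sites <- as.integer(n_sites)
  if (missing(seed)) stop("seed is mandatory")
  withSeed(seed, {
    chrom <- rep_len(1:22, n_sites)
    chrom <- sort(chrom)
    pos <- unlist(lapply(split(seq_len(n_sites), chrom),
                         function(i) spacing_bp * seq_along(i)),
                  use.names = FALSE)
    freq <- freq_sampler(n_sites)
    if (any(freq <= 0 | freq >= 1))
      stop("freq_sampler must yield values strictly inside (0, 1)")
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
    SitePanel(site_id = sprintf("snp_%d_%d", chrom, pos),
              chrom = chrom, pos = pos, ref = ref, alt = alt,
              alt_freq = freq)
  })
}

#' SitePanel accessors
#'
#' @param x a [SitePanel-class] (or a container whose `rowRanges` is one).
#' @return `siteIDs`, `refAllele`, `altAllele`, `altFreq` return the
#'   corresponding per-site vector.
#' @name panel-accessors
NULL

panelOf <- function(x) {
  if (is(x, "GRanges")) x else rowRanges(x)
}

#' @rdname panel-accessors
#' @export
siteIDs <- function(x) mcols(panelOf(x))$site_id

#' @rdname panel-accessors
#' @export
refAllele <- function(x) mcols(panelOf(x))$ref

#' @rdname panel-accessors
#' @export
altAllele <- function(x) mcols(panelOf(x))$alt

#' @rdname panel-accessors
#' @export
altFreq <- function(x) mcols(panelOf(x))$alt_freq

# sites whose ref/alt pairing is affected by terminal deamination
# (C->T and its reverse-strand counterpart G->A, in either role)
deaminationProne <- function(panel) {
  r <- refAllele(panel); a <- altAllele(panel)
  (r == "C" & a == "T") | (r == "T" & a == "C") |
    (r == "G" & a == "A") | (r == "A" & a == "G")
}

setMethod("show", "SitePanel", function(object) {
  cat(sprintf("SitePanel with %d sites on %d chromosome(s); alt_freq in [%.3f, %.3f]\n",
              length(object), length(unique(as.character(seqnames(object)))),
              min(altFreq(object)), max(altFreq(object))))
  callNextMethod()
})
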