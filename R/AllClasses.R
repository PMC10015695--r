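#' @import methods
#' @importFrom stats rbinom rpois runif sd cor setNames qnorm pnorm
#' @importFrom utils combn read.table write.table
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData
#' @importFrom Rcpp sourceCpp
#' @useDynLib kinlow, .registration = TRUE
NULL

DEGREE_LEVELS <- c("identical", "first", "second", "third", "unrelated")

#' Panel of biallelic SNP sites with population allele frequencies
#'
#' A `SitePanel` is a [GenomicRanges::GRanges] of width-1 biallelic sites with
#' metadata columns `site_id`, `ref`, `alt` (single nucleotides) and
#' `alt_freq` (population alternative-allele frequency, strictly inside
#' (0, 1)). It stands in for an ascertained capture panel such as the
#' "1240k" SNP set that low-coverage kinship analyses are restricted to.
#'
#' @slot .  inherits all slots from `GRanges`.
#' @seealso [SitePanel()], [simulatePanel()], [readPanel()]
#' @export
setClass("SitePanel", contains = "GRanges")

setValidity("SitePanel", function(object) {
  mc <- mcols(object)
  need <- c("site_id", "ref", "alt", "alt_freq")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (anyDuplicated(mc$site_id))
    return("site_id values must be unique")
  if (any(mc$alt_freq <= 0 | mc$alt_freq >= 1))
    return("alt_freq must lie strictly inside (0, 1)")
  nt <- c("A", "C", "G", "T")
  if (!all(mc$ref %in% nt) || !all(mc$alt %in% nt))
    return("ref/alt must be single nucleotides A/C/G/T")
  if (any(mc$ref == mc$alt))
    return("ref and alt must differ at every site")
  # positions strictly increasing within each chromosome
  pos_ok <- vapply(split(start(object), as.character(seqnames(object))),
                   function(p) all(diff(p) > 0), logical(1))
  if (!all(pos_ok))
    return("positions must be strictly increasing within a chromosome")
  TRUE
})

#' Pedigree of individuals with optional monozygotic duplicates
#'
#' Founders have no parents; every non-founder has exactly two parents that
#' are themselves in the pedigree. An individual may instead be flagged as a
#' duplicate of another genome (`duplicate_of`), which models a monozygotic
#' twin or a resequenced library of the same individual: it receives an
#' identical genome in simulation and kinship 0.5 with its original.
#'
#' @slot id character vector of unique individual identifiers.
#' @slot mother,father character vectors aligned with `id`; `NA` for
#'   founders and duplicates.
#' @slot duplicate_of character vector aligned with `id`; `NA` unless the
#'   individual is a copy of another (non-duplicate) individual's genome.
#' @seealso [Pedigree()], [trueKinship()], [simulateGenotypes()]
#' @export
setClass("Pedigree",
  representation(id = "character", mother = "character",
                 father = "character", duplicate_of = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@mother) != n || length(object@father) != n ||
      length(object@duplicate_of) != n)
    return("id, mother, father and duplicate_of must have equal length")
  if (anyDuplicated(object@id)) return("individual ids must be unique")
  one_parent <- xor(is.na(object@mother), is.na(object@father))
  if (any(one_parent))
    return(paste("individual(s) with exactly one recorded parent:",
                 paste(object@id[one_parent], collapse = ", ")))
  pars <- c(object@mother, object@father)
  if (!all(pars[!is.na(pars)] %in% object@id))
    return("all parents must be individuals in the pedigree")
  dups <- object@duplicate_of
  has_dup <- !is.na(dups)
  if (any(has_dup & (!is.na(object@mother))))
    return("a duplicate individual cannot also have parents")
  if (!all(dups[has_dup] %in% object@id))
    return("duplicate_of must name an individual in the pedigree")
  if (any(dups[has_dup] %in% object@id[has_dup]))
    return("duplicate_of must point to a non-duplicate individual")
  if (is.null(topoOrder(object)))
    return("parent graph must be acyclic")
  TRUE
})

# topological order of ids (parents before children); NULL if cyclic
topoOrder <- function(ped) {
  ids <- ped@id
  placed <- character(0)
  remaining <- ids
  while (length(remaining)) {
    i <- match(remaining, ids)
    ready <- (is.na(ped@mother[i]) |
                (ped@mother[i] %in% placed & ped@father[i] %in% placed)) &
             (is.na(ped@duplicate_of[i]) | ped@duplicate_of[i] %in% placed)
    if (!any(ready)) return(NULL)
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' Assay container classes
#'
#' Thin [SummarizedExperiment::RangedSummarizedExperiment] subclasses keeping
#' sites as rows (with the `SitePanel` as `rowRanges`) and individuals as
#' columns:
#'
#' * `GenotypeMatrix` — assay `geno`: true diploid alternative-allele counts
#'   in \{0, 1, 2\} (the latent truth behind simulated reads).
#' * `ReadPileup` — assays `ref`, `alt`: non-negative per-site read counts;
#'   the unit that binomial read thinning operates on.
#' * `PseudohaploidCalls` — assay `call`: 0 (ref), 1 (alt), `NA` exactly
#'   where pileup depth is zero.
#' * `GLMatrix` — assays `L0`, `L1`, `L2`: genotype likelihood triples
#'   normalised to sum 1; all-`NA` triples flag sites with no reads.
#'
#' @name kinlow-containers
#' @aliases GenotypeMatrix-class ReadPileup-class PseudohaploidCalls-class
#'   GLMatrix-class
NULL

#' @rdname kinlow-containers
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

#' @rdname kinlow-containers
#' @export
setClass("ReadPileup", contains = "RangedSummarizedExperiment")

#' @rdname kinlow-containers
#' @export
setClass("PseudohaploidCalls", contains = "RangedSummarizedExperiment")

#' @rdname kinlow-containers
#' @export
setClass("GLMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"geno" %in% names(assays(object))) return("assay 'geno' required")
  g <- assay(object, "geno")
  if (anyNA(g) || !all(g %in% 0:2))
    return("genotypes must be complete and in {0,1,2}")
  TRUE
})

setValidity("ReadPileup", function(object) {
  if (!all(c("ref", "alt") %in% names(assays(object))))
    return("assays 'ref' and 'alt' required")
  r <- assay(object, "ref"); a <- assay(object, "alt")
  if (anyNA(r) || anyNA(a) || any(r < 0) || any(a < 0))
    return("read counts must be non-negative and complete")
  TRUE
})

setValidity("PseudohaploidCalls", function(object) {
  if (!"call" %in% names(assays(object))) return("assay 'call' required")
  cl <- assay(object, "call")
  if (!all(cl %in% c(0L, 1L, NA)))
    return("calls must be 0 (ref), 1 (alt) or NA (missing)")
  TRUE
})

setValidity("GLMatrix", function(object) {
  if (!all(c("L0", "L1", "L2") %in% names(assays(object))))
    return("assays 'L0', 'L1', 'L2' required")
  s <- assay(object, "L0") + assay(object, "L1") + assay(object, "L2")
  ok <- is.na(s) | abs(s - 1) < 1e-9
  if (!all(ok)) return("non-missing likelihood triples must sum to 1")
  neg <- !is.na(s) & (assay(object, "L0") < 0 | assay(object, "L1") < 0 |
                        assay(object, "L2") < 0)
  if (any(neg)) return("likelihoods must be non-negative")
  TRUE
})
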