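se_build <- function(class, assays, panel, individuals) {
  assays <- lapply(assays, function(m) {
    dimnames(m) <- list(siteIDs(panel), individuals)
    m
  })
  se <- SummarizedExperiment(
    assays = assays,
    rowRanges = as(panel, "GRanges"),
    colData = DataFrame(individual = individuals, row.names = individuals))
  new(class, se)
}

#' @rdname kinlow-containers
#' @param geno integer matrix (sites x individuals) of alt-allele counts.
#' @param panel the [SitePanel-class] the rows refer to.
#' @param individuals column (individual) ids.
#' @export
GenotypeMatrix <- function(geno, panel, individuals = colnames(geno)) {
  se_build("GenotypeMatrix", list(geno = geno), panel, individuals)
}

#' @rdname kinlow-containers
#' @param ref,alt integer matrices (sites x individuals) of reference- and
#'   alternative-allele read counts.
#' @export
ReadPileup <- function(ref, alt, panel, individuals = colnames(ref)) {
  se_build("ReadPileup", list(ref = ref, alt = alt), panel, individuals)
}

#' @rdname kinlow-containers
#' @param call integer matrix of pseudohaploid calls (0/1/NA).
#' @export
PseudohaploidCalls <- function(call, panel, individuals = colnames(call)) {
  se_build("PseudohaploidCalls", list(call = call), panel, individuals)
}

#' @rdname kinlow-containers
#' @param L0,L1,L2 numeric matrices of normalised genotype likelihoods.
#' @export
GLMatrix <- function(L0, L1, L2, panel, individuals = colnames(L0)) {
  se_build("GLMatrix", list(L0 = L0, L1 = L1, L2 = L2), panel, individuals)
}

#' Assay accessors
#'
#' @param x a container object.
#' @return The assay matrix (sites x individuals).
#' @name assay-accessors
NULL

#' @rdname assay-accessors
#' @export
genotypes <- function(x) assay(x, "geno")

#' @rdname assay-accessors
#' @export
refCounts <- function(x) assay(x, "ref")

#' @rdname assay-accessors
#' @export
altCounts <- function(x) assay(x, "alt")

#' @rdname assay-accessors
#' @export
phCalls <- function(x) assay(x, "call")

#' @rdname assay-accessors
#' @export
likelihoods <- function(x) {
  list(L0 = assay(x, "L0"), L1 = assay(x, "L1"), L2 = assay(x, "L2"))
}

#' @rdname assay-accessors
#' @export
individuals <- function(x) colnames(x)

setMethod("show", "ReadPileup", function(object) {
  d <- refCounts(object) + altCounts(object)
  cat(sprintf("ReadPileup: %d sites x %d individuals; mean depth %.3f; %.1f%% sites covered\n",
              nrow(object), ncol(object), mean(d), 100 * mean(d > 0)))
})

setMethod("show", "PseudohaploidCalls", function(object) {
  cl <- phCalls(object)
  cat(sprintf("PseudohaploidCalls: %d sites x %d individuals; %.1f%% called\n",
              nrow(object), ncol(object), 100 * mean(!is.na(cl))))
})

setMethod("show", "GLMatrix", function(object) {
  m <- is.na(assay(object, "L1"))
  cat(sprintf("GLMatrix: %d sites x %d individuals; %.1f%% informative\n",
              nrow(object), ncol(object), 100 * mean(!m)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d sites x %d individuals; mean alt dosage %.3f\n",
              nrow(object), ncol(object), mean(genotypes(object))))
})
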