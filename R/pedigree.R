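#' Construct a Pedigree
#'
#' @param id character vector of unique individual ids.
#' @param mother,father character vectors (recycled `NA` by default) naming
#'   each individual's parents; founders leave both `NA`. An individual with
#'   exactly one recorded parent is rejected.
#' @param duplicate_of optional character vector flagging individuals that
#'   carry an identical copy of another individual's genome (monozygotic
#'   twin / resequenced library).
#' @return A [Pedigree-class] object.
#' @examples
#' trio <- Pedigree(id = c("mo", "fa", "ch"),
#'                  mother = c(NA, NA, "mo"), father = c(NA, NA, "fa"))
#' @export
Pedigree <- function(id, mother = NA, father = NA, duplicate_of = NA) {
  n <- length(id)
  new("Pedigree", id = as.character(id),
      mother = as.character(rep_len(mother, n)),
      father = as.character(rep_len(father, n)),
      duplicate_of = as.character(rep_len(duplicate_of, n)))
}

#' @describeIn Pedigree ids of all individuals.
#' @param object,x a `Pedigree`.
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' Individual ids of a pedigree
#' @param ped a [Pedigree-class].
#' @return Character vector of ids.
#' @export
pedIDs <- function(ped) ped@id

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@mother) & is.na(object@duplicate_of))
  cat(sprintf("Pedigree with %d individuals (%d founders, %d duplicates)\n",
              length(object@id), nf, sum(!is.na(object@duplicate_of))))
})

## ---- shipped fixture pedigrees ------------------------------------------

#' Fixture pedigrees for benchmarking
#'
#' Four pedigrees with the relationship structure of the cohorts commonly
#' analysed in low-coverage kinship studies:
#'
#' * `pedigreeTrios()` — 15 individuals in five independent
#'   father--mother--offspring trios (modern trio cohort stand-in). The ten
#'   parent--offspring pairs are first degree; spouses are unrelated.
#' * `pedigreeFamily()` — a 15-individual extended family containing an
#'   identical pair (monozygotic copy), first-degree (parent--offspring and
#'   full siblings), second-degree (grandparent, avuncular), third-degree
#'   (great-grandparent, first cousins) and unrelated pairs.
#' * `pedigreeUnrelated(n)` — `n` mutually unrelated founders (default 5;
#'   stand-in for a cohort reported as containing no relatives).
#' * `pedigreeCohort()` — 28 individuals, mostly unrelated, with a handful
#'   of relatives (one trio and one parent--offspring pair).
#'
#' @param n number of founders for `pedigreeUnrelated`.
#' @return A [Pedigree-class].
#' @name fixture-pedigrees
NULL

#' @rdname fixture-pedigrees
#' @export
pedigreeTrios <- function() {
  fam <- function(k)
    data.frame(id = paste0(c("fa", "mo", "ch"), k),
               mother = c(NA, NA, paste0("mo", k)),
               father = c(NA, NA, paste0("fa", k)))
  d <- do.call(rbind, lapply(1:5, fam))
  Pedigree(d$id, d$mother, d$father)
}

#' @rdname fixture-pedigrees
#' @export
pedigreeFamily <- function() {
  # A,B -> C,D (sibs); C+E -> G; G+H -> I; D+J -> K; L = copy of G;
  # M,N,O,P unrelated founders.  Degrees present: identical (G-L),
  # first (A-C, C-D, C-G, ...), second (A-G, D-G), third (A-I, G-K, K-I),
  # unrelated (M-N, ...).
  Pedigree(
    id          = c("A", "B", "C", "D", "E", "G", "H", "I", "J", "K",
                    "L", "M", "N", "O", "P"),
    mother      = c(NA, NA, "A", "A", NA, "C", NA, "G", NA, "D",
                    NA, NA, NA, NA, NA),
    father      = c(NA, NA, "B", "B", NA, "E", NA, "H", NA, "J",
                    NA, NA, NA, NA, NA),
    duplicate_of = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                     "G", NA, NA, NA, NA))
}

#' @rdname fixture-pedigrees
#' @export
pedigreeUnrelated <- function(n = 5) {
  Pedigree(sprintf("u%02d", seq_len(n)))
}

#' @rdname fixture-pedigrees
#' @export
pedigreeCohort <- function() {
  ids <- sprintf("v%02d", 1:23)
  d <- data.frame(id = ids, mother = NA_character_, father = NA_character_)
  extra <- data.frame(
    id     = c("vfa", "vmo", "vch", "wpa", "wch"),
    mother = c(NA, NA, "vmo", NA, "v01"),
    father = c(NA, NA, "vfa", NA, "wpa"))
  d <- rbind(d, extra)
  Pedigree(d$id, d$mother, d$father)
}

## ---- true kinship --------------------------------------------------------

# full kinship matrix by the recursive (tabular) algorithm; duplicates are
# assigned their original's rows/columns and self-kinship with the original
kinshipMatrixRaw <- function(ped) {
  ord <- topoOrder(ped)
  ids <- ped@id
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (id in ord) {
    i <- match(id, ids)
    dup <- ped@duplicate_of[i]
    if (!is.na(dup)) {
      d <- match(dup, ids)
      phi[i, ] <- phi[d, ]
      phi[, i] <- phi[, d]
      phi[i, d] <- phi[d, i] <- phi[d, d]
      phi[i, i] <- phi[d, d]
      next
    }
    mo <- ped@mother[i]; fa <- ped@father[i]
    if (is.na(mo)) {
      phi[i, i] <- 0.5
    } else {
      m <- match(mo, ids); f <- match(fa, ids)
      done <- match(ord[seq_len(match(id, ord) - 1)], ids)
      phi[i, done] <- 0.5 * (phi[m, done] + phi[f, done])
      phi[done, i] <- phi[i, done]
      phi[i, i] <- 0.5 * (1 + phi[m, f])
    }
  }
  phi
}

checkOutbred <- function(ped, phi) {
  nonf <- which(!is.na(ped@mother))
  for (i in nonf) {
    m <- match(ped@mother[i], ped@id); f <- match(ped@father[i], ped@id)
    if (phi[m, f] > 0)
      stop("inbred pedigree: parents of '", ped@id[i],
           "' are related; only outbred pedigrees are supported")
  }
  invisible(TRUE)
}

#' True kinship coefficient and degree for a pair
#'
#' Computes the pedigree kinship coefficient phi — the probability that one
#' allele sampled from each individual at an autosomal locus is identical by
#' descent — by the standard recursion
#' `phi(a, b) = (phi(mother(a), b) + phi(father(a), b)) / 2` with founder
#' base cases, and assigns the relationship degree (0.5 identical, 0.25
#' first, 0.125 second, 0.0625 third, 0 unrelated for outbred pedigrees).
#' Inbred pedigrees are rejected.
#'
#' @param ped a [Pedigree-class].
#' @param pair character vector of two ids.
#' @return A list with `pair` (sorted ids), `phi` and `degree`.
#' @examples
#' trio <- pedigreeTrios()
#' trueKinship(trio, c("fa1", "ch1"))$phi   # 0.25
#' @export
trueKinship <- function(ped, pair) {
  stopifnot(length(pair) == 2)
  if (!all(pair %in% ped@id))
    stop("pair ids must be in the pedigree")
  phi <- kinshipMatrixRaw(ped)
  checkOutbred(ped, phi)
  v <- if (pair[1] == pair[2]) phi[pair[1], pair[1]] else phi[pair[1], pair[2]]
  # a duplicated genome shares both alleles IBD: phi = self-kinship = 0.5
  if (pair[1] != pair[2]) {
    d1 <- ped@duplicate_of[match(pair[1], ped@id)]
    d2 <- ped@duplicate_of[match(pair[2], ped@id)]
    if ((!is.na(d1) && d1 == pair[2]) || (!is.na(d2) && d2 == pair[1]))
      v <- 0.5
  }
  list(pair = sort(pair), phi = unname(v), degree = degreeFromPhi(v))
}

#' Pairwise true kinship table for a pedigree
#'
#' @param ped a [Pedigree-class] (outbred).
#' @return A data.frame with one row per unordered pair: `id1`, `id2`,
#'   `pair` key, `phi`, `degree`, and `related` (degree second or closer,
#'   the binary relatedness threshold used throughout the benchmark).
#' @export
truthTable <- function(ped) {
  phi <- kinshipMatrixRaw(ped)
  checkOutbred(ped, phi)
  pr <- allPairs(ped@id)
  v <- phi[cbind(pr[, 1], pr[, 2])]
  # duplicates: phi with their original is the full self-kinship
  for (i in which(!is.na(ped@duplicate_of))) {
    id <- ped@id[i]; orig <- ped@duplicate_of[i]
    hit <- (pr[, 1] == id & pr[, 2] == orig) | (pr[, 2] == id & pr[, 1] == orig)
    v[hit] <- phi[orig, orig]
  }
  deg <- degreeFromPhi(v)
  data.frame(id1 = pr[, 1], id2 = pr[, 2], pair = pairKey(pr[, 1], pr[, 2]),
             phi = v, degree = deg,
             related = deg %in% c("identical", "first", "second"),
             stringsAsFactors = FALSE)
}
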