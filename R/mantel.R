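permutationsAll <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsAll(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)), deparse.level = 0)
  }))
}

upperVec <- function(m) m[upper.tri(m)]

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the vectorised upper triangles, with a two-sided
#' permutation test jointly permuting rows and columns of the second
#' matrix: `p = (1 + # permutations with |r_perm| >= |r_obs|) / (n_perm + 1)`.
#' For matrices of size 6 or smaller the full permutation distribution is
#' enumerated instead and p is the exact tail proportion (including the
#' identity). If either matrix has zero variance the result is flagged
#' degenerate with `r = NA`.
#'
#' @param a,b symmetric numeric matrices of equal size (n >= 4) with zero
#'   diagonals.
#' @param n_perm number of random permutations (default 9999; ignored for
#'   exact enumeration).
#' @param seed integer seed for the permutation draw.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` enumerates exactly whenever n <= 6.
#' @return A list: `r`, `p`, `n_perm` (permutations actually used), `n`
#'   (matrix size), `exact` (logical), `degenerate` (logical).
#' @examples
#' m <- as.matrix(dist(1:5)); mantelTest(m, m, seed = 1)$r   # 1
#' @export
mantelTest <- function(a, b, n_perm = 9999, seed, exact = NULL) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)) ||
      nrow(a) != ncol(a))
    stop("a and b must be square matrices of the same size")
  if (max(abs(a - t(a))) > 1e-9 || max(abs(b - t(b))) > 1e-9)
    stop("a and b must be symmetric")
  if (any(abs(diag(a)) > 1e-9) || any(abs(diag(b)) > 1e-9))
    stop("a and b must have zero diagonals")
  n <- nrow(a)
  if (n < 4) stop("need matrices of size at least 4")
  va <- upperVec(a)
  if (sd(va) == 0 || sd(upperVec(b)) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = 0L, n = n,
                exact = FALSE, degenerate = TRUE))
  r_obs <- cor(va, upperVec(b))
  if (is.null(exact)) exact <- n <= 6
  if (exact) {
    perms <- permutationsAll(n)
    r_all <- apply(perms, 1, function(pm) cor(va, upperVec(b[pm, pm])))
    p <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
    return(list(r = r_obs, p = p, n_perm = nrow(perms), n = n,
                exact = TRUE, degenerate = FALSE))
  }
  hits <- withSeed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      pm <- sample.int(n)
      abs(cor(va, upperVec(b[pm, pm]))) >= abs(r_obs) - 1e-12
    }, logical(1)))
  })
  list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = as.integer(n_perm),
       n = n, exact = FALSE, degenerate = FALSE)
}
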