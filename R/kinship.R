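# Relationship matrices: pedigree (numerator) and genomic (marker-based).

#' Numerator relationship matrix from a pedigree
#'
#' Computes A by the tabular method: `A_ii = 1 + F_i` with `F_i` half the
#' relationship between the parents, and
#' `A_ij = (A_{i,sire(j)} + A_{i,dam(j)}) / 2` for i preceding j. Parents
#' must be listed before their offspring; unknown parents are `NA`.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (character;
#'   `NA` for unknown parents).
#' @return symmetric matrix with `id` dimnames.
#' @export
numerator_relationship_matrix <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  id <- as.character(pedigree$id)
  assert_that(!anyDuplicated(id), "duplicated ids in pedigree")
  s <- match(as.character(pedigree$sire), id)
  d <- match(as.character(pedigree$dam), id)
  known_s <- !is.na(as.character(pedigree$sire))
  known_d <- !is.na(as.character(pedigree$dam))
  assert_that(all(!known_s | !is.na(s)) && all(!known_d | !is.na(d)),
              "pedigree refers to parents absent from the id column")
  n <- length(id)
  assert_that(all(is.na(s) | s < seq_len(n)) && all(is.na(d) | d < seq_len(n)),
              "parents must precede offspring in the pedigree")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (j in seq_len(n)) {
    sj <- s[j]; dj <- d[j]
    if (j > 1) {
      i <- seq_len(j - 1)
      as_ <- if (is.na(sj)) 0 else A[i, sj]
      ad_ <- if (is.na(dj)) 0 else A[i, dj]
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
    A[j, j] <- 1 + if (!is.na(sj) && !is.na(dj)) 0.5 * A[sj, dj] else 0
  }
  A
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = Xc Xc' k` with `Xc` the 0/1/2 genotype matrix column-centred by twice
#' the allele frequency and `k = 1 / (2 * sum_j p_j (1 - p_j))`. The mean
#' diagonal is about 1 in an unstructured Hardy-Weinberg population.
#'
#' @param X genotype matrix (individuals x markers, entries 0/1/2, no
#'   missing values).
#' @param p optional vector of allele frequencies; defaults to
#'   `colMeans(X) / 2`. Supply training-set frequencies when building
#'   cross-set blocks.
#' @return symmetric positive semi-definite matrix.
#' @export
genomic_relationship_matrix <- function(X, p = NULL) {
  assert_that(!anyNA(X), "X contains missing values; impute first")
  p <- p %||% (colMeans(X) / 2)
  k <- 2 * sum(p * (1 - p))
  assert_that(k > 0, "all markers are monomorphic; G undefined")
  Xc <- sweep(X, 2, 2 * p)
  (Xc %*% t(Xc)) / k
}

# Cross-set relationship block rows = new individuals, cols = training set,
# using training allele frequencies (no leakage).
genomic_cross_block <- function(X_new, X_train, p) {
  k <- 2 * sum(p * (1 - p))
  (sweep(X_new, 2, 2 * p) %*% t(sweep(X_train, 2, 2 * p))) / k
}
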