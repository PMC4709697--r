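# Shared design container for the genomic prediction models.

#' Assemble a genomic-prediction design
#'
#' Bundles phenotypes, the 0/1/2 marker design matrix, and the family
#' incidence used as fixed effects by all models (`y = mu + Z w + X g + e`).
#' Missing genotypes must be imputed beforehand (see [impute_mean()]); the
#' family term is dropped automatically when there is a single family.
#'
#' @param y phenotype vector.
#' @param X genotype matrix, individuals x markers, entries in \[0, 2\]
#'   (fractional values from mean imputation are allowed).
#' @param families optional factor/vector of family labels.
#' @param pedigree optional pedigree data.frame (`id`, `sire`, `dam`) for
#'   pedigree BLUP.
#' @param tbv optional vector of true breeding values (simulations only).
#' @return a `gs_data` object.
#' @export
gs_data <- function(y, X, families = NULL, pedigree = NULL, tbv = NULL) {
  X <- as.matrix(X)
  assert_that(length(y) == nrow(X), "y and X are not conformable")
  assert_that(!anyNA(y), "y contains missing values")
  assert_that(!anyNA(X), "X contains missing genotypes; impute first")
  assert_that(all(X >= 0 & X <= 2), "X entries must lie in [0, 2]")
  if (!is.null(families)) {
    families <- factor(families)
    assert_that(length(families) == length(y), "families length mismatch")
    if (nlevels(families) < 2) families <- NULL
  }
  W <- if (is.null(families)) matrix(1, length(y), 1,
                                     dimnames = list(NULL, "(Intercept)"))
       else model.matrix(~families)
  p <- colMeans(X) / 2
  structure(list(y = as.numeric(y), X = X, families = families, W = W,
                 p = p, pedigree = pedigree, tbv = tbv),
            class = "gs_data")
}

#' @export
print.gs_data <- function(x, ...) {
  cat(sprintf("gs_data: %d records x %d markers, %s\n",
              length(x$y), ncol(x$X),
              if (is.null(x$families)) "single family"
              else paste(nlevels(x$families), "families")))
  invisible(x)
}

# Centered marker matrix (by 2p of the training data).
centered_X <- function(data) sweep(data$X, 2, 2 * data$p)

new_gs_fit <- function(method, data, beta, g = NULL, gebv, varcomp,
                       alpha = NULL, pip = NULL, diagnostics = NULL,
                       extra = list()) {
  structure(c(list(method = method, beta = beta, g = g, gebv = gebv,
                   varcomp = varcomp, alpha = alpha, pip = pip,
                   diagnostics = diagnostics,
                   p = data$p, W_names = colnames(data$W),
                   family_levels = if (is.null(data$families)) NULL
                                   else levels(data$families),
                   Xc_train = if (is.null(alpha)) NULL else centered_X(data)),
              extra),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit [%s]: %d training GEBVs", x$method, length(x$gebv)))
  if (!is.null(x$g)) cat(sprintf(", %d marker effects", length(x$g)))
  cat("\n")
  vc <- x$varcomp
  if (!is.null(vc$sigma_a2))
    cat(sprintf("  sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
                vc$sigma_a2, vc$sigma_e2,
                vc$sigma_a2 / (vc$sigma_a2 + vc$sigma_e2)))
  invisible(x)
}
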