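# BLUP-family estimators: pedigree BLUP, G-BLUP and RR-BLUP. All three share
# the mixed model y = W b + u + e with u ~ N(0, sigma_a^2 K); they differ in
# K (pedigree A vs marker G) and in whether marker effects are recovered
# explicitly (RR-BLUP). Variance components come from the shared REML
# routine, estimated on the training records only.

kinship_blup <- function(data, K, method) {
  reml <- estimate_h2_reml(data$y, K, data$W)
  n <- length(data$y)
  V <- reml$sigma_a2 * K + diag(reml$sigma_e2, n)
  alpha <- solve(V, data$y - drop(data$W %*% reml$beta))
  gebv <- drop(reml$sigma_a2 * K %*% alpha)
  new_gs_fit(method, data,
             beta = setNames(reml$beta, colnames(data$W)),
             gebv = gebv,
             varcomp = list(sigma_a2 = reml$sigma_a2,
                            sigma_e2 = reml$sigma_e2, h2 = reml$h2,
                            se_h2 = reml$se_h2),
             alpha = reml$sigma_a2 * alpha)
}

#' Pedigree BLUP
#'
#' Best linear unbiased prediction of breeding values with the covariance of
#' genetic effects given by the pedigree numerator relationship matrix A.
#' Equivalent to G-BLUP with A substituted for the genomic matrix (same
#' solver). Variance components are estimated by REML on the supplied
#' records.
#'
#' @param data a [gs_data] object with a pedigree, or pass `A` directly.
#' @param A optional precomputed numerator relationship matrix for the
#'   records in `data` (rows in record order). Required if `data$pedigree`
#'   does not cover exactly the records.
#' @return a `gs_fit` (no per-marker effects).
#' @export
fit_pedigree_blup <- function(data, A = NULL) {
  stopifnot(inherits(data, "gs_data"))
  if (is.null(A)) {
    assert_that(!is.null(data$pedigree), "pedigree BLUP requires a pedigree or A")
    A <- numerator_relationship_matrix(data$pedigree)
    A <- A[seq_along(data$y), seq_along(data$y)]
  }
  kinship_blup(data, A, "BLUP")
}

#' G-BLUP
#'
#' Pedigree BLUP with the numerator relationship matrix replaced by the
#' marker-based genomic relationship matrix (VanRaden).
#'
#' @param data a [gs_data] object.
#' @param G optional precomputed genomic relationship matrix; defaults to
#'   [genomic_relationship_matrix()] of `data$X`.
#' @return a `gs_fit`; GEBVs are the BLUPs of the genomic values.
#' @export
fit_gblup <- function(data, G = NULL) {
  stopifnot(inherits(data, "gs_data"))
  G <- G %||% genomic_relationship_matrix(data$X, data$p)
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(diag(G)))
    stop("G is not PSD beyond tolerance; consider blending G with the identity")
  kinship_blup(data, G, "G-BLUP")
}

#' RR-BLUP (ridge regression BLUP)
#'
#' Ridge regression of phenotypes on all markers with common shrinkage
#' `lambda = sigma_e^2 / (sigma_g^2)` where `sigma_g^2 = sigma_a^2 / k` and
#' `k = sum_j 2 p_j (1 - p_j)`. Solved through the n x n dual system, so it
#' remains cheap when markers far outnumber records. With variance
#' components shared with [fit_gblup()], the GEBVs are algebraically
#' identical to G-BLUP.
#'
#' @param data a [gs_data] object.
#' @param varcomp optional list with `sigma_a2`, `sigma_e2` (e.g. from a
#'   previous REML fit); estimated by REML on `data` when missing.
#' @return a `gs_fit` with per-marker effects `g`.
#' @export
fit_rrblup <- function(data, varcomp = NULL) {
  stopifnot(inherits(data, "gs_data"))
  k <- 2 * sum(data$p * (1 - data$p))
  assert_that(k > 0, "all markers monomorphic")
  Xc <- centered_X(data)
  if (is.null(varcomp)) {
    G <- (Xc %*% t(Xc)) / k
    reml <- estimate_h2_reml(data$y, G, data$W)
    varcomp <- list(sigma_a2 = reml$sigma_a2, sigma_e2 = reml$sigma_e2,
                    h2 = reml$h2, beta = reml$beta)
  }
  beta <- varcomp$beta
  if (is.null(beta)) {
    G <- (Xc %*% t(Xc)) / k
    V <- varcomp$sigma_a2 * G + diag(varcomp$sigma_e2, nrow(Xc))
    Vi <- solve(V)
    beta <- drop(solve(t(data$W) %*% Vi %*% data$W + diag(1e-10, ncol(data$W)),
                       t(data$W) %*% Vi %*% data$y))
  }
  sigma_g2 <- varcomp$sigma_a2 / k
  lambda <- varcomp$sigma_e2 / sigma_g2
  ystar <- data$y - drop(data$W %*% beta)
  n <- nrow(Xc)
  # dual ridge solution: g = Xc' (Xc Xc' + lambda I)^-1 y*
  a <- solve(Xc %*% t(Xc) + diag(lambda, n), ystar)
  g <- drop(t(Xc) %*% a)
  new_gs_fit("RR-BLUP", data, beta = setNames(beta, colnames(data$W)),
             g = setNames(g, colnames(data$X)),
             gebv = drop(Xc %*% g),
             varcomp = c(varcomp[c("sigma_a2", "sigma_e2", "h2")],
                         list(lambda = lambda, k = k)))
}

#' Predict breeding values for new individuals
#'
#' Marker-effect methods (RR-BLUP, Bayes alphabet, LASSO) return
#' `Xc_new g_hat` with centring by the training allele frequencies.
#' Kinship-based fits (pedigree BLUP, G-BLUP) project through the
#' relationship block between the new and training individuals.
#'
#' @param fit a `gs_fit`.
#' @param X_new genotype matrix of the new individuals on the training
#'   marker panel (imputed).
#' @param K_cross optional relationship block (new x training) for
#'   kinship-based fits; computed from `X_new` and the stored training
#'   genotypes for G-BLUP when omitted.
#' @param families_new optional family labels; when provided (and seen in
#'   training) the estimated family effect is added to the prediction.
#' @return numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, X_new = NULL, K_cross = NULL,
                         families_new = NULL) {
  stopifnot(inherits(fit, "gs_fit"))
  if (!is.null(fit$g)) {
    assert_that(!is.null(X_new), "marker-effect prediction requires X_new")
    assert_that(ncol(X_new) == length(fit$g),
                "X_new does not match the training marker panel")
    pred <- drop(sweep(X_new, 2, 2 * fit$p) %*% fit$g)
  } else {
    if (is.null(K_cross)) {
      assert_that(!is.null(X_new) && !is.null(fit$Xc_train),
                  "kinship-based prediction requires K_cross or X_new")
      assert_that(ncol(X_new) == ncol(fit$Xc_train),
                  "X_new does not match the training marker panel")
      k <- 2 * sum(fit$p * (1 - fit$p))
      K_cross <- (sweep(X_new, 2, 2 * fit$p) %*% t(fit$Xc_train)) / k
    }
    assert_that(ncol(K_cross) == length(fit$alpha),
                "K_cross must have one column per training record")
    pred <- drop(K_cross %*% fit$alpha)
  }
  pred + family_effect(fit, families_new)
}

# Estimated family effect for new individuals (0 for unseen families, the
# reference family, or a fit without a family term).
family_effect <- function(fit, families_new) {
  if (is.null(families_new) || is.null(fit$family_levels)) return(0)
  fam <- factor(families_new, levels = fit$family_levels)
  eff <- c(0, fit$beta[-1])[as.integer(fam)]
  eff[is.na(eff)] <- 0
  eff
}
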