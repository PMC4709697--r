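# REML estimation of variance components for the single-random-effect model
#   y = W b + u + e,  u ~ N(0, sigma_a^2 K),  e ~ N(0, sigma_e^2 I)
# via eigen-decomposition of the projected relationship matrix, profiling the
# likelihood over the variance ratio.

#' REML heritability estimation
#'
#' Estimates `sigma_a^2`, `sigma_e^2` and `h2 = sigma_a^2 / (sigma_a^2 +
#' sigma_e^2)` by restricted maximum likelihood. The REML log-likelihood is
#' profiled over the ratio `lambda = sigma_a^2 / sigma_e^2` using the
#' spectral decomposition of `S K S` (S the projection removing the fixed
#' effects), then maximised with one-dimensional search on `log(lambda)`.
#' Standard errors come from the numerical observed information of the
#' restricted likelihood, with the h2 standard error by the delta method.
#'
#' @param y phenotype vector.
#' @param K relationship matrix (pedigree A or genomic G), PSD.
#' @param W fixed-effect design matrix; defaults to an intercept. Pass a
#'   family incidence design to absorb family means.
#' @return list with `sigma_a2`, `sigma_e2`, `h2`, `se_h2`, `se_sigma_a2`,
#'   `se_sigma_e2`, `beta` (GLS fixed effects), `loglik`, `lambda`,
#'   `boundary` (TRUE when the estimate hit the search boundary).
#' @export
estimate_h2_reml <- function(y, K, W = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  qrW <- qr(W)
  q <- qrW$rank
  # orthonormal basis of the complement of col(W); restricting to it gives
  # the REML (error) contrasts and stays valid when K is rank-deficient
  U0 <- qr.Q(qrW, complete = TRUE)[, (q + 1):n, drop = FALSE]
  M <- t(U0) %*% K %*% U0
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  xi <- pmax(ee$values, 0)
  eta <- drop(crossprod(ee$vectors, drop(crossprod(U0, y))))
  m <- n - q

  rll <- function(loglam) {
    lam <- exp(loglam)
    d <- lam * xi + 1
    s2 <- sum(eta^2 / d) / m
    -0.5 * (m * log(2 * pi * s2) + m + sum(log(d)))
  }
  lo <- -12; hi <- 12
  opt <- optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lam <- exp(opt$maximum)
  boundary <- opt$maximum < lo + 0.05 || opt$maximum > hi - 0.05
  d <- lam * xi + 1
  sigma_e2 <- sum(eta^2 / d) / m
  sigma_a2 <- lam * sigma_e2
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)

  # restricted log-likelihood as a function of (sigma_a2, sigma_e2)
  rll2 <- function(va, ve) {
    dd <- va * xi + ve
    if (any(dd <= 0)) return(-Inf)
    -0.5 * (m * log(2 * pi) + sum(log(dd)) + sum(eta^2 / dd))
  }
  hstep <- c(max(sigma_a2, 1e-6), max(sigma_e2, 1e-6)) * 1e-3
  Hmat <- matrix(NA_real_, 2, 2)
  f0 <- rll2(sigma_a2, sigma_e2)
  pt <- c(sigma_a2, sigma_e2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    if (i == j) {
      Hmat[i, j] <- (rll2(pt[1] + ei[1], pt[2] + ei[2]) - 2 * f0 +
                       rll2(pt[1] - ei[1], pt[2] - ei[2])) / hstep[i]^2
    } else {
      Hmat[i, j] <- (rll2(pt[1] + ei[1] + ej[1], pt[2] + ei[2] + ej[2]) -
                       rll2(pt[1] + ei[1] - ej[1], pt[2] + ei[2] - ej[2]) -
                       rll2(pt[1] - ei[1] + ej[1], pt[2] - ei[2] + ej[2]) +
                       rll2(pt[1] - ei[1] - ej[1], pt[2] - ei[2] - ej[2])) /
        (4 * hstep[i] * hstep[j])
    }
  }
  se <- c(NA_real_, NA_real_); se_h2 <- NA_real_
  Vcov <- try(solve(-Hmat), silent = TRUE)
  if (!inherits(Vcov, "try-error") && all(diag(Vcov) > 0)) {
    se <- sqrt(diag(Vcov))
    grad <- c(sigma_e2, -sigma_a2) / (sigma_a2 + sigma_e2)^2
    se_h2 <- sqrt(drop(t(grad) %*% Vcov %*% grad))
  }

  # GLS fixed effects at the REML estimates
  V <- sigma_a2 * K + diag(sigma_e2, n)
  Vi <- solve(V)
  beta <- drop(solve(t(W) %*% Vi %*% W + diag(1e-10, ncol(W)),
                     t(W) %*% Vi %*% y))
  list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2,
       se_h2 = se_h2, se_sigma_a2 = se[1], se_sigma_e2 = se[2],
       beta = beta, loglik = opt$objective, lambda = lam,
       boundary = boundary)
}
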