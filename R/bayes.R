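# Bayesian whole-genome regressions: BayesA, BayesB and the Bayesian LASSO,
# fitted by single-site Gibbs sampling (C++ core). Marker effects get
# locus-specific shrinkage: scaled-inverse-chi-square variances (BayesA), a
# point mass at zero with probability pi plus the BayesA slab (BayesB), or a
# double-exponential prior represented as a normal scale mixture (BL).

#' MCMC hyperparameters for the Bayesian regressions
#'
#' Defaults: 10,000 iterations with 2,000 burn-in and thinning 5; prior
#' degrees of freedom `nu = 4.2` for the locus variances with scale `S`
#' derived from the phenotypic variance (half the variance attributed to
#' markers a priori); `pi_zero = 0.95` for BayesB. The residual variance has
#' a scaled-inverse-chi-square prior with `nue = 4` and scale matched to half
#' the phenotypic variance. The BL penalty `lambda^2` gets a diffuse Gamma
#' hyperprior updated by its full conditional unless `lambda2` is fixed.
#'
#' @param niter,burnin,thin chain length, burn-in and thinning.
#' @param nu,S prior df and scale for locus variances (S = NULL derives it
#'   from the data).
#' @param pi_zero BayesB prior probability of a zero effect, in \[0, 1).
#' @param nue,Se residual-variance prior df and scale (Se = NULL derives it).
#' @param lambda2 initial (or fixed) BL penalty squared.
#' @param lambda_fixed keep `lambda2` fixed instead of sampling it.
#' @param lambda_shape,lambda_rate Gamma hyperprior for `lambda2`.
#' @param seed optional integer seed (chains are bit-reproducible).
#' @return list of class `gs_hyper`.
#' @export
gs_hyper <- function(niter = 10000, burnin = 2000, thin = 5,
                     nu = 4.2, S = NULL, pi_zero = 0.95,
                     nue = 4, Se = NULL, lambda2 = 1,
                     lambda_fixed = FALSE, lambda_shape = 0.1,
                     lambda_rate = 0.1, seed = NULL) {
  assert_that(niter > burnin, "chain length must exceed burn-in")
  assert_that(pi_zero >= 0 && pi_zero < 1, "pi_zero must lie in [0, 1)")
  structure(list(niter = niter, burnin = burnin, thin = thin, nu = nu,
                 S = S, pi_zero = pi_zero, nue = nue, Se = Se,
                 lambda2 = lambda2, lambda_fixed = lambda_fixed,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                 seed = seed),
            class = "gs_hyper")
}

# Split-chain potential scale reduction on a single scalar chain.
split_rhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 4) return(NA_real_)
  a <- x[seq_len(m)]; b <- x[m + seq_len(m)]
  W <- (var(a) + var(b)) / 2
  B <- m * var(c(mean(a), mean(b)))
  if (W <= 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

run_bayes <- function(data, hyper, method_code, method_name, pi_zero) {
  stopifnot(inherits(data, "gs_data"))
  vy <- var(data$y)
  p <- ncol(data$X)
  k <- 2 * sum(data$p * (1 - data$p))
  S <- hyper$S %||% {
    # prior locus variance with mean 0.5 * var(y) / ((1 - pi) * sum 2pq)
    vg <- 0.5 * vy / max((1 - pi_zero) * k, 1e-8)
    vg * (hyper$nu - 2) / hyper$nu
  }
  Se <- hyper$Se %||% (0.5 * vy * (hyper$nue - 2) / hyper$nue)
  Xc <- centered_X(data)
  res <- with_seed(hyper$seed, {
    bayes_gibbs_cpp(data$y, Xc, data$W,
                    as.integer(hyper$niter), as.integer(hyper$burnin),
                    as.integer(hyper$thin), hyper$nu, S, pi_zero,
                    hyper$nue, Se, as.integer(method_code),
                    hyper$lambda2, hyper$lambda_shape, hyper$lambda_rate,
                    hyper$lambda_fixed)
  })
  g <- setNames(res$g, colnames(data$X))
  diagnostics <- list(n_saved = res$n_saved,
                      chain = list(niter = hyper$niter,
                                   burnin = hyper$burnin, thin = hyper$thin),
                      rhat_sigma_e2 = split_rhat(res$sigma_e2_chain),
                      sigma_e2_chain = res$sigma_e2_chain)
  new_gs_fit(method_name, data,
             beta = setNames(res$b, colnames(data$W)),
             g = g, gebv = drop(Xc %*% g),
             varcomp = list(sigma_e2 = res$sigma_e2,
                            sigma_g2_locus = res$sigma_g2_locus,
                            lambda2 = if (method_code == 2) res$lambda2 else NULL,
                            prior = list(nu = hyper$nu, S = S,
                                         pi_zero = pi_zero,
                                         nue = hyper$nue, Se = Se)),
             pip = if (method_code == 1) res$pip else NULL,
             diagnostics = diagnostics)
}

#' BayesA
#'
#' Whole-genome regression in which every marker effect has its own variance
#' with a scaled-inverse-chi-square prior; marginally the effects are
#' scaled-t distributed. Posterior means by Gibbs sampling.
#'
#' @param data a [gs_data] object.
#' @param hyper a [gs_hyper()] configuration.
#' @return a `gs_fit` with posterior-mean marker effects.
#' @export
fit_bayesA <- function(data, hyper = gs_hyper()) {
  run_bayes(data, hyper, 0L, "BayesA", pi_zero = 0)
}

#' BayesB
#'
#' Spike-and-slab extension of BayesA: a marker effect is exactly zero with
#' prior probability `pi_zero` and BayesA-distributed otherwise. Inclusion
#' indicators are sampled from the marginal likelihood ratio with the effect
#' integrated out; posterior inclusion probabilities are reported. BayesA is
#' recovered at `pi_zero = 0`.
#'
#' @inheritParams fit_bayesA
#' @return a `gs_fit` with `pip` (posterior inclusion probabilities).
#' @export
fit_bayesB <- function(data, hyper = gs_hyper()) {
  run_bayes(data, hyper, 1L, "BayesB", pi_zero = hyper$pi_zero)
}

#' Bayesian LASSO
#'
#' Marker effects carry a double-exponential prior, represented as a normal
#' scale mixture with exponential mixing variances; the residual variance has
#' a scaled-inverse-chi-square prior. The penalty `lambda` is given a Gamma
#' hyperprior by default (or fixed via `gs_hyper(lambda2 =, lambda_fixed =
#' TRUE)`).
#'
#' @inheritParams fit_bayesA
#' @return a `gs_fit`.
#' @export
fit_bayesian_lasso <- function(data, hyper = gs_hyper()) {
  run_bayes(data, hyper, 2L, "BL", pi_zero = 0)
}
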