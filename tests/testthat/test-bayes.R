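# Gibbs samplers: BayesA, BayesB and the Bayesian LASSO, checked against
# conjugate/enumerable/quadrature oracles with pinned nuisance variances.

# Hyperparameters that pin sigma_e2 (huge prior df) and, when requested, the
# locus variance (huge nu with S at the target).
pinned_hyper <- function(sigma_e2, sigma_g2 = NULL, niter = 4000,
                         burnin = 1000, pi_zero = 0.95, seed = 1) {
  gs_hyper(niter = niter, burnin = burnin, thin = 1,
           nu = if (is.null(sigma_g2)) 4.2 else 1e7,
           S = if (is.null(sigma_g2)) NULL else sigma_g2,
           pi_zero = pi_zero,
           nue = 1e8, Se = sigma_e2, seed = seed)
}

test_that("BayesA single-marker posterior matches the conjugate closed form", {
  set.seed(21)
  n <- 60
  x <- rbinom(n, 2, 0.5)
  g_true <- 1.2
  se2 <- 1; sg2 <- 0.8
  y <- x * g_true + rnorm(n, 0, sqrt(se2))
  d <- gs_data(y, matrix(x, ncol = 1))
  f <- fit_bayesA(d, pinned_hyper(se2, sg2, niter = 8000, burnin = 2000))
  # with both variances pinned the posterior of g is normal:
  xc <- x - mean(x) # sampler centres by 2p = mean(x)
  # account for the intercept: g | y ~ N(xc'yc / (xc'xc + se2/sg2), .)
  yc <- y - mean(y)
  post_mean <- sum(xc * yc) / (sum(xc^2) + se2 / sg2)
  expect_lt(abs(f$g[1] - post_mean), 0.05)
})

test_that("BayesA shrinks to zero on pure-noise data", {
  # markers far outnumber records, the usual whole-genome regression regime
  # in which the prior spreads the assumed genetic variance thinly
  set.seed(22)
  X <- hwe_genotypes(200, runif(2364, 0.2, 0.8), seed = 23)
  y <- rnorm(200)
  f <- fit_bayesA(gs_data(y, X), gs_hyper(niter = 2000, burnin = 500,
                                          thin = 1, seed = 24))
  expect_lt(max(abs(f$g)), 0.05 * sd(y))
})

test_that("BayesA approaches RR-BLUP in the matched large-nu limit", {
  td <- toy_family_data(seed = 505, n_families = 4, family_size = 20,
                        burnin_gen = 60)
  d <- gs_data(td$y, td$X, families = td$families)
  fr <- fit_rrblup(d)
  sg2 <- fr$varcomp$sigma_a2 / fr$varcomp$k
  fa <- fit_bayesA(d, pinned_hyper(fr$varcomp$sigma_e2, sg2,
                                   niter = 6000, burnin = 1500, seed = 25))
  expect_gt(cor(fa$gebv, fr$gebv), 0.99)
})

test_that("BayesB with pi = 0 reproduces BayesA", {
  td <- toy_family_data(seed = 506, n_families = 4, family_size = 20,
                        burnin_gen = 60)
  d <- gs_data(td$y, td$X, families = td$families)
  h <- gs_hyper(niter = 3000, burnin = 800, thin = 1, pi_zero = 0, seed = 26)
  fa <- fit_bayesA(d, h)
  fb <- fit_bayesB(d, h)
  expect_gt(cor(fa$gebv, fb$gebv), 0.99)
  informative <- colSums(sweep(td$X, 2, colMeans(td$X))^2) > 0
  expect_true(all(fb$pip[informative] == 1))
})

test_that("BayesB keeps nearly all indicators off on null data", {
  set.seed(27)
  X <- hwe_genotypes(100, runif(80, 0.2, 0.8), seed = 28)
  y <- rnorm(100)
  f <- fit_bayesB(gs_data(y, X),
                  gs_hyper(niter = 2000, burnin = 500, thin = 1,
                           pi_zero = 0.99, seed = 29))
  expect_lt(mean(f$pip), 0.05)
})

test_that("BayesB inclusion probabilities match exhaustive enumeration", {
  # two markers, variances pinned: the posterior over the four indicator
  # configurations is computable in closed form from the marginal likelihood
  # y ~ N(0, se2 I + sum_in sg2 x_j x_j')
  set.seed(30)
  n <- 40
  X <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.4))
  se2 <- 1; sg2 <- 1; pi0 <- 0.5
  y <- X[, 1] * 0.9 + rnorm(n, 0, 1)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  logml <- function(incl) {
    V <- diag(se2, n)
    for (j in which(incl)) V <- V + sg2 * tcrossprod(Xc[, j])
    as.numeric(mvn_logdens(yc, V))
  }
  mvn_logdens <- function(v, V) {
    ch <- chol(V)
    -0.5 * (length(v) * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, v, transpose = TRUE)^2))
  }
  configs <- expand.grid(c(FALSE, TRUE), c(FALSE, TRUE))
  lp <- apply(configs, 1, function(cf) {
    logml(as.logical(cf)) + sum(ifelse(as.logical(cf), log(1 - pi0), log(pi0)))
  })
  post <- exp(lp - max(lp)); post <- post / sum(post)
  pip_exact <- c(sum(post[configs[, 1]]), sum(post[configs[, 2]]))

  f <- fit_bayesB(gs_data(y, X),
                  pinned_hyper(se2, sg2, niter = 12000, burnin = 2000,
                               pi_zero = pi0, seed = 31))
  expect_lt(max(abs(f$pip - pip_exact)), 0.05)
})

test_that("Bayesian LASSO shrinks null data and responds to the penalty", {
  set.seed(32)
  X <- hwe_genotypes(200, runif(2364, 0.2, 0.8), seed = 33)
  y <- rnorm(200)
  f <- fit_bayesian_lasso(gs_data(y, X),
                          gs_hyper(niter = 3000, burnin = 800, thin = 1,
                                   seed = 34))
  expect_lt(max(abs(f$g)), 0.05 * sd(y))

  # monotone shrinkage in lambda on fixed signal data
  td <- toy_family_data(seed = 507, n_families = 4, family_size = 20,
                        burnin_gen = 60)
  d <- gs_data(td$y, td$X, families = td$families)
  norms <- vapply(c(1, 50, 2000), function(l2) {
    fl <- fit_bayesian_lasso(d, gs_hyper(niter = 2000, burnin = 500,
                                         thin = 1, lambda2 = l2,
                                         lambda_fixed = TRUE, seed = 35))
    sqrt(sum(fl$g^2))
  }, numeric(1))
  expect_true(norms[1] > norms[2] && norms[2] > norms[3])
})

test_that("Bayesian LASSO single-marker posterior matches 1-D quadrature", {
  set.seed(36)
  n <- 50
  x <- rbinom(n, 2, 0.5)
  se2 <- 1
  lambda2 <- 9 # lambda = 3
  y <- x * 0.8 + rnorm(n, 0, 1)
  xc <- x - mean(x); yc <- y - mean(y)
  # posterior density: N(yc | xc g, se2 I) * DE(g | rate lambda / sqrt(se2))
  lam <- sqrt(lambda2)
  logpost <- function(g) {
    -sum((yc - xc * g)^2) / (2 * se2) - lam * abs(g) / sqrt(se2)
  }
  gs <- seq(-2, 3, length.out = 4001)
  w <- exp(vapply(gs, logpost, numeric(1)))
  post_mean <- sum(gs * w) / sum(w)
  f <- fit_bayesian_lasso(gs_data(y, matrix(x, ncol = 1)),
                          pinned_hyper(se2, niter = 12000, burnin = 2000,
                                       seed = 37))
  f2 <- fit_bayesian_lasso(gs_data(y, matrix(x, ncol = 1)),
                           gs_hyper(niter = 12000, burnin = 2000, thin = 1,
                                    nue = 1e8, Se = se2, lambda2 = lambda2,
                                    lambda_fixed = TRUE, seed = 37))
  expect_lt(abs(f2$g[1] - post_mean), 0.05)
  expect_s3_class(f, "gs_fit")
})

test_that("chains are bit-reproducible for a fixed seed and report diagnostics", {
  td <- toy_family_data(seed = 508, n_families = 4, family_size = 15,
                        burnin_gen = 50)
  d <- gs_data(td$y, td$X, families = td$families)
  h <- gs_hyper(niter = 800, burnin = 200, thin = 2, seed = 38)
  f1 <- fit_bayesA(d, h)
  f2 <- fit_bayesA(d, h)
  expect_identical(f1$g, f2$g)
  expect_identical(f1$diagnostics$sigma_e2_chain, f2$diagnostics$sigma_e2_chain)
  expect_true(is.finite(f1$diagnostics$rhat_sigma_e2))
  expect_lt(f1$diagnostics$rhat_sigma_e2, 1.2)
})
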