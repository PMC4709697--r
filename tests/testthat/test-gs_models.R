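# The seven estimators, relationship matrices and REML.

test_that("numerator relationship matrix reproduces textbook values", {
  founders <- data.frame(id = c("a", "b"), sire = NA, dam = NA)
  expect_equal(unname(numerator_relationship_matrix(founders)), diag(2))

  ped <- data.frame(id = c("s", "d", "o1", "o2"),
                    sire = c(NA, NA, "s", "s"),
                    dam = c(NA, NA, "d", "d"))
  A <- numerator_relationship_matrix(ped)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["o1", "o1"], 1)
  expect_equal(A["s", "o1"], 0.5)

  # 3-generation pedigree vs a recursive coancestry oracle
  ped3 <- data.frame(id = c("a", "b", "c", "d", "e", "f", "g"),
                     sire = c(NA, NA, NA, "a", "a", "d", "d"),
                     dam = c(NA, NA, NA, "b", "c", "e", "e"))
  A3 <- numerator_relationship_matrix(ped3)
  s <- setNames(match(ped3$sire, ped3$id), ped3$id)
  d <- setNames(match(ped3$dam, ped3$id), ped3$id)
  kin <- function(i, j) { # recursive kinship; A = 2 * kinship
    if (i == j) {
      si <- s[i]; di <- d[i]
      return(0.5 * (1 + if (!is.na(si) && !is.na(di)) kin(si, di) else 0))
    }
    if (i < j) { tmp <- i; i <- j; j <- tmp } # i is the later individual
    si <- s[i]; di <- d[i]
    0.5 * ((if (!is.na(si)) kin(si, j) else 0) +
             (if (!is.na(di)) kin(di, j) else 0))
  }
  for (i in 1:7) for (j in 1:7) {
    expect_equal(A3[i, j], 2 * kin(i, j) * if (i == j) 1 else 1,
                 tolerance = 1e-12,
                 label = sprintf("A[%d,%d]", i, j))
  }

  bad <- data.frame(id = c("x", "y"), sire = c("y", NA), dam = c(NA, NA))
  expect_error(numerator_relationship_matrix(bad), "precede")
})

test_that("genomic relationship matrix matches a naive loop and HWE scaling", {
  X <- hwe_genotypes(20, runif(50, 0.1, 0.9), seed = 2)
  G <- genomic_relationship_matrix(X)
  p <- colMeans(X) / 2
  k <- 2 * sum(p * (1 - p))
  G2 <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    G2[i, j] <- sum((X[i, ] - 2 * p) * (X[j, ] - 2 * p)) / k
  }
  expect_equal(unname(G), G2, tolerance = 1e-12)
  expect_true(isSymmetric(G))

  # duplicated individuals have identical rows and G_ii = G_ij
  Xd <- rbind(X, X[1, ])
  Gd <- genomic_relationship_matrix(Xd)
  expect_equal(Gd[1, 21], Gd[1, 1])
  expect_equal(Gd[1, ], Gd[21, ])

  # unrelated HWE population: mean diagonal about 1
  Xb <- hwe_genotypes(300, runif(2000, 0.1, 0.9), seed = 3)
  Gb <- genomic_relationship_matrix(Xb)
  expect_lt(abs(mean(diag(Gb)) - 1), 0.05)

  expect_error(genomic_relationship_matrix(matrix(2, 5, 4)), "monomorphic")
  expect_error(genomic_relationship_matrix(matrix(c(NA, 1, 1, 0), 2)), "missing")
})

test_that("REML is scale-equivariant and hits the boundary on pure noise", {
  set.seed(5)
  X <- hwe_genotypes(200, runif(400, 0.1, 0.9), seed = 6)
  G <- genomic_relationship_matrix(X)
  u <- drop(t(chol(G + diag(1e-6, 200))) %*% rnorm(200))
  y <- 3 + u + rnorm(200, 0, 1)
  r1 <- estimate_h2_reml(y, G)
  r2 <- estimate_h2_reml(10 * y, G)
  expect_equal(r1$h2, r2$h2, tolerance = 1e-4)
  expect_equal(r2$sigma_a2, 100 * r1$sigma_a2, tolerance = 1e-2)

  # error-free phenotype (y = genetic value): the variance ratio runs to the
  # upper search boundary and is flagged rather than erroring
  rb <- estimate_h2_reml(u, G)
  expect_true(rb$boundary)
  expect_gt(rb$h2, 0.99)
})

test_that("pedigree BLUP equals G-BLUP run on the same relationship matrix", {
  td <- toy_family_data(seed = 501)
  ped_all <- rbind(
    data.frame(id = unique(c(td$pop$ped$sire, td$pop$ped$dam)),
               sire = NA_character_, dam = NA_character_),
    td$pop$ped[, c("id", "sire", "dam")])
  A <- numerator_relationship_matrix(ped_all)
  An <- A[td$pop$ped$id, td$pop$ped$id]
  data <- gs_data(td$y, td$X, families = td$families, pedigree = ped_all)
  f1 <- fit_pedigree_blup(data, A = An)
  f2 <- fit_gblup(data, G = An)
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-10)
  expect_equal(f1$varcomp$h2, f2$varcomp$h2, tolerance = 1e-10)
})

test_that("pedigree BLUP solves Henderson's mixed model equations", {
  td <- toy_family_data(seed = 502, n_families = 4, family_size = 12,
                        burnin_gen = 60)
  ped_all <- rbind(
    data.frame(id = unique(c(td$pop$ped$sire, td$pop$ped$dam)),
               sire = NA_character_, dam = NA_character_),
    td$pop$ped[, c("id", "sire", "dam")])
  A_full <- numerator_relationship_matrix(ped_all)
  An <- A_full[td$pop$ped$id, td$pop$ped$id]
  data <- gs_data(td$y, td$X, families = td$families)
  fit <- fit_pedigree_blup(data, A = An)
  # independent oracle: MME at the same variance components
  lam <- fit$varcomp$sigma_e2 / fit$varcomp$sigma_a2
  W <- model.matrix(~factor(td$families))
  n <- length(td$y)
  LHS <- rbind(cbind(crossprod(W), t(W)),
               cbind(W, diag(n) + solve(An) * lam))
  RHS <- c(crossprod(W, td$y), td$y)
  sol <- solve(LHS, RHS)
  u_mme <- sol[(ncol(W) + 1):length(sol)]
  expect_equal(unname(fit$gebv), unname(u_mme), tolerance = 1e-6)
})

test_that("null data shrink BLUP-family predictions toward zero", {
  set.seed(7)
  X <- hwe_genotypes(120, runif(300, 0.1, 0.9), seed = 8)
  y <- rnorm(120)
  d <- gs_data(y, X)
  f <- fit_gblup(d)
  expect_lt(sd(f$gebv), 0.5 * sd(y))
})

test_that("RR-BLUP equals the dense ridge closed form and G-BLUP GEBVs", {
  set.seed(9)
  X <- hwe_genotypes(30, runif(100, 0.1, 0.9), seed = 10)
  y <- drop(scale(X[, 1:5]) %*% rnorm(5)) + rnorm(30)
  d <- gs_data(y, X)
  fr <- fit_rrblup(d)
  # dense primal solve at the same lambda and fixed effects
  Xc <- sweep(X, 2, 2 * d$p)
  ystar <- y - fr$beta[1]
  g_dense <- solve(crossprod(Xc) + diag(fr$varcomp$lambda, 100),
                   crossprod(Xc, ystar))
  expect_equal(unname(fr$g), drop(g_dense), tolerance = 1e-8)

  fg <- fit_gblup(d)
  expect_equal(fr$gebv, fg$gebv, tolerance = 1e-8)

  # huge lambda: effects vanish
  f0 <- fit_rrblup(d, varcomp = list(sigma_a2 = 1e-10, sigma_e2 = 1,
                                     beta = fr$beta))
  expect_lt(max(abs(f0$g)), 1e-6)
})

test_that("predict_gebv reproduces training GEBVs and the duality", {
  td <- toy_family_data(seed = 503)
  d <- gs_data(td$y, td$X, families = td$families)
  fr <- fit_rrblup(d)
  fg <- fit_gblup(d)
  expect_equal(predict_gebv(fr, td$X), fr$gebv, tolerance = 1e-10)
  # G-BLUP projection through the cross block equals RR-BLUP prediction
  Xnew <- td$X[1:20, , drop = FALSE]
  expect_equal(predict_gebv(fg, Xnew), predict_gebv(fr, Xnew),
               tolerance = 1e-8)
  # zero effects give zero predictions
  fr0 <- fr; fr0$g[] <- 0
  expect_equal(unname(predict_gebv(fr0, Xnew)), rep(0, 20))
  expect_error(predict_gebv(fr, td$X[, 1:3]), "panel")
})

test_that("GLS estimating equations hold at the fitted fixed effects", {
  td <- toy_family_data(seed = 504)
  d <- gs_data(td$y, td$X, families = td$families)
  f <- fit_gblup(d)
  G <- genomic_relationship_matrix(td$X)
  V <- f$varcomp$sigma_a2 * G + diag(f$varcomp$sigma_e2, length(td$y))
  resid <- td$y - drop(d$W %*% f$beta)
  score <- crossprod(d$W, solve(V, resid))
  expect_lt(max(abs(score)) / length(td$y), 1e-6)
})
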