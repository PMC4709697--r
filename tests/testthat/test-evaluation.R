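# QC, imputation, cross-validation mechanics, accuracy metrics and
# diagnostics.

test_that("qc_filter applies the MAF and call-rate thresholds", {
  # 6 individuals x 4 markers, engineered around the thresholds
  X <- rbind(c(0, 0, 2, 1),
             c(1, 0, 2, 1),
             c(0, 0, 2, NA),
             c(0, 0, 2, NA),
             c(1, 0, NA, 1),
             c(0, 1, NA, 1))
  colnames(X) <- paste0("m", 1:4)
  # m1: maf 2/12=0.167, call 1.00 -> keep
  # m2: maf 1/12=0.083, call 1.00 -> keep
  # m3: maf 0 (monomorphic), call 4/6 -> drop (MAF)
  # m4: call 4/6 = 0.667 < 0.70 -> drop (call rate)
  q <- qc_filter(X)
  expect_identical(colnames(q$genotypes), c("m1", "m2"))
  expect_equal(q$stats$call_rate, c(1, 1, 4 / 6, 4 / 6))

  # threshold edges on 50 individuals: allele counts 4/100 = MAF 0.04
  # (removed), 6/100 = MAF 0.06 (kept); call rate 32/50 = 0.64 (removed)
  X3 <- cbind(maf04 = c(rep(1, 4), rep(0, 46)),
              maf06 = c(rep(1, 6), rep(0, 44)),
              lowcall = c(rep(NA, 18), rep(c(0, 1), 16)))
  q3 <- qc_filter(X3)
  expect_identical(colnames(q3$genotypes), "maf06")
  expect_false(q3$keep[["maf04"]])
  expect_false(q3$keep[["lowcall"]]) # call rate 32/50 = 0.64 < 0.70
  expect_error(qc_filter(matrix(0, 5, 3)), "all markers")
})

test_that("mean imputation preserves observed values and column means", {
  X <- cbind(c(0, 2, NA), c(1, NA, 1))
  Xi <- impute_mean(X)
  expect_equal(Xi[3, 1], 1)
  expect_equal(Xi[2, 2], 1)
  expect_equal(colMeans(Xi), colMeans(X, na.rm = TRUE))
  expect_identical(impute_mean(Xi), Xi)
  expect_error(impute_mean(cbind(c(NA, NA), c(1, 2))), "missing")
  # validation imputation uses supplied (training) means
  Xv <- impute_mean(X, means = c(0.5, 0.25))
  expect_equal(Xv[3, 1], 0.5)
})

test_that("fold assignment partitions every individual once per repeat", {
  set.seed(51)
  f <- radgs:::make_folds(53, 5)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) %in% c(10, 11)))
  fam <- rep(1:4, each = 20)
  fs <- radgs:::make_folds(80, 5, fam, "family")
  expect_true(all(table(fs, fam) == 4))
})

test_that("cross-validation is leakage-free and null-calibrated", {
  td <- toy_family_data(seed = 510, n_families = 4, family_size = 20,
                        burnin_gen = 60)
  # permuting validation phenotypes after the split leaves accuracy (vs
  # truth) unchanged: the training-fold fit cannot see validation data
  tr <- rep(TRUE, 80); tr[1:16] <- FALSE
  y2 <- td$y
  y2[!tr] <- sample(y2[!tr])
  a1 <- radgs:::eval_split(td$y, td$X, "G-BLUP", tr, td$tbv, td$families,
                           NULL, gs_hyper(), FALSE)
  a2 <- radgs:::eval_split(y2, td$X, "G-BLUP", tr, td$tbv, td$families,
                           NULL, gs_hyper(), FALSE)
  expect_equal(a1$accuracy, a2$accuracy, tolerance = 1e-10)

  # EBV independent of truth: mean accuracy near zero
  set.seed(52)
  res <- cross_validate(rnorm(80), td$X, "G-BLUP",
                        cv_scheme(k = 5, repeats = 4, seed = 53),
                        truth = rnorm(80))
  expect_lt(abs(mean(res$accuracy, na.rm = TRUE)), 0.2)
  expect_equal(nrow(res), 20) # k folds x repeats rows per method
})

test_that("over-generation evaluation reduces to training accuracy on a copy", {
  td <- toy_family_data(seed = 511, n_families = 4, family_size = 20,
                        burnin_gen = 60)
  r <- over_generation_eval(td$y, td$X, td$X, td$tbv, c("RR-BLUP", "G-BLUP"))
  d <- gs_data(td$y, td$X)
  f <- fit_rrblup(d)
  expect_equal(r$accuracy[r$method == "RR-BLUP"], cor(td$tbv, f$gebv),
               tolerance = 1e-8)
  expect_equal(r$accuracy[r$method == "RR-BLUP"],
               r$accuracy[r$method == "G-BLUP"], tolerance = 1e-6)
  expect_error(over_generation_eval(td$y, td$X, td$X[, 1:5], td$tbv, "G-BLUP"),
               "match")
})

test_that("adjusted accuracy follows r / sqrt(h2)", {
  expect_equal(adjusted_accuracy(0.36, 0.36), 0.60)
  expect_equal(adjusted_accuracy(0.37, 0.48), 0.37 / sqrt(0.48),
               tolerance = 1e-12)
  expect_equal(round(adjusted_accuracy(0.37, 0.48), 2), 0.53)
  expect_equal(adjusted_accuracy(0, 0.2), 0)
  expect_equal(adjusted_accuracy(0.5, 1), 0.5) # h2 = 1: no adjustment
  expect_warning(adjusted_accuracy(0.9, 0.25), "exceeds 1")
  expect_error(adjusted_accuracy(0.3, 0), "positive")
})

test_that("bias slope behaves as a regression of phenotype on EBV", {
  set.seed(54)
  ebv <- rnorm(200)
  expect_equal(bias_slope(ebv, ebv), 1, tolerance = 1e-12)
  y <- 2 * ebv + rnorm(200, 0, 0.1)
  expect_equal(bias_slope(y, ebv), 2, tolerance = 0.05)
  expect_error(bias_slope(y, rep(1, 200)), "constant")
})

test_that("pca matches the covariance eigendecomposition", {
  set.seed(55)
  M <- matrix(rnorm(60), 10, 6)
  p <- pca(M, 3)
  ev <- eigen(cov(M))
  expect_equal((p$sdev^2)[1:3], ev$values[1:3], tolerance = 1e-8)
  expect_equal(abs(as.numeric(cor(p$scores[, 1],
                                  scale(M, scale = FALSE) %*% ev$vectors[, 1]))),
               1, tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lt(abs(sum(crossprod(p$scores)[upper.tri(diag(3))])), 1e-8)

  # rank-1 matrix: first component explains everything
  r1 <- tcrossprod(rnorm(8), rnorm(5))
  p1 <- pca(r1, 2)
  expect_gt(p1$explained_variance[1], 0.999)
  expect_error(pca(M, 11), "fewer rows")
  expect_error(pca(cbind(c(1, NA), c(0, 1)), 1), "complete")
})

test_that("marker-effect correlations form a valid symmetric matrix", {
  td <- toy_family_data(seed = 512, n_families = 4, family_size = 15,
                        burnin_gen = 50)
  d <- gs_data(td$y, td$X, families = td$families)
  fr <- fit_rrblup(d)
  fl <- suppressWarnings(fit_lasso(d, lambda = 0.05))
  C <- marker_effect_correlation(list(`RR-BLUP` = fr, LASSO = fl, again = fr))
  expect_equal(diag(C), c(`RR-BLUP` = 1, LASSO = 1, again = 1))
  expect_equal(C, t(C))
  expect_equal(C["RR-BLUP", "again"], 1, tolerance = 1e-12)
  # zero-variance vector gives NA off-diagonals
  f0 <- fr; f0$g[] <- 0
  C0 <- marker_effect_correlation(list(a = fr, b = f0))
  expect_true(is.na(C0["a", "b"]))
})

test_that("run_experiment produces a reproducible long-format table", {
  cfg <- list(design = "sim2", h2 = 0.4, methods = c("G-BLUP", "RR-BLUP"),
              replicates = 1, cv = list(k = 3, repeats = 1),
              scale = list(n_families = 4, family_size = 15, n_markers = 200,
                           n_qtl = 60, n_chrom = 5, chrom_cm = 25,
                           burnin_n = 100, burnin_gen = 100),
              seed = 99)
  r1 <- run_experiment(cfg)
  expect_equal(nrow(r1$results), 3 * 2) # folds x methods
  expect_true(all(c("accuracy", "slope", "method", "h2") %in%
                    names(r1$results)))
  r2 <- run_experiment(cfg)
  expect_identical(r1$results$accuracy, r2$results$accuracy)
  expect_equal(nrow(r1$summary), 2)
  expect_error(validate_run_config(c(cfg, list(bogus = 1))), "unknown")
})
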