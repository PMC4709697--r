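# Replicated reproduction harness for the headline simulation experiments:
# the population-based design (Table-2-style cells), the family-based design
# (Table-3-style grid) and the dominance comparison. Each function simulates
# independent replicates and returns fold-level accuracies in long format;
# the acceptance script and tests average them. MCMC chains are short
# (800 iterations) because posterior-mean GEBVs stabilise quickly; the
# methods vignette documents this choice.

bench_hyper <- function(seed = NULL) {
  gs_hyper(niter = 800, burnin = 250, thin = 1, seed = seed)
}

#' Replicated accuracy benchmark: population-based design
#'
#' For each replicate, builds the population-scale study ([sim1_study()]) and
#' evaluates three headline cells: five-fold CV of BayesA on the LD panel at
#' h2 = 0.5, five-fold CV of BayesA on the MD panel at h2 = 0.2, and
#' over-generation (train G1, predict G2) G-BLUP on the LD panel at
#' h2 = 0.1.
#'
#' @param seed master seed.
#' @param replicates number of independent simulation replicates.
#' @param sim overrides passed to [sim1_study()].
#' @return long data.frame: replicate, panel, h2, method, setting
#'   ("cv" or "over_generation"), accuracy.
#' @export
benchmark_sim1 <- function(seed, replicates = 10, sim = list()) {
  seeds <- derive_seeds(seed, replicates * 2)
  out <- list()
  for (r in seq_len(replicates)) {
    st <- do.call(sim1_study, c(list(seed = seeds[r]), sim))
    gv1 <- genetic_values(st$G1, st$arch)
    gv2 <- genetic_values(st$G2, st$arch)
    X1 <- genotypes(st$G1)
    X2 <- genotypes(st$G2)
    s2 <- seeds[replicates + r]

    cells <- list(
      list(panel = "LD", h2 = 0.5, method = "BayesA", setting = "cv"),
      list(panel = "MD", h2 = 0.2, method = "BayesA", setting = "cv"),
      list(panel = "LD", h2 = 0.1, method = "G-BLUP",
           setting = "over_generation"))
    for (cl in cells) {
      ph <- simulate_phenotypes(gv1$tbv, h2 = cl$h2,
                                seed = s2 + round(1000 * cl$h2))
      cols <- st$panels[[cl$panel]]
      if (cl$setting == "cv") {
        # population-based design: no family term (see the methods vignette)
        res <- cross_validate(ph$phenotype, X1[, cols, drop = FALSE],
                              cl$method, cv_scheme(5, 1, seed = s2),
                              truth = gv1$tbv,
                              hyper = bench_hyper(s2))
      } else {
        res <- over_generation_eval(ph$phenotype, X1[, cols, drop = FALSE],
                                    X2[, cols, drop = FALSE], gv2$tbv,
                                    cl$method, hyper = bench_hyper(s2))
      }
      out[[length(out) + 1]] <- data.frame(
        replicate = r, panel = cl$panel, h2 = cl$h2, method = cl$method,
        setting = cl$setting, accuracy = res$accuracy)
    }
  }
  do.call(rbind, out)
}

#' Replicated accuracy benchmark: family-based design
#'
#' For each replicate, builds the 20-family study ([sim2_study()]) and
#' evaluates (a) five-fold CV of BayesB on all 20 families at h2 = 0.1 and
#' (b) five-fold CV of G-BLUP, BayesA and BayesB on the first 5 families at
#' h2 in `h2_grid`.
#'
#' @param seed master seed.
#' @param replicates number of replicates.
#' @param h2_grid heritabilities for the 5-family grid.
#' @param sim overrides passed to [sim2_study()].
#' @return long data.frame: replicate, n_families, h2, method, accuracy.
#' @export
benchmark_sim2 <- function(seed, replicates = 10,
                           h2_grid = c(0.2, 0.3, 0.4, 0.5), sim = list()) {
  seeds <- derive_seeds((seed %% 1000000000L) + 1L, replicates * 2)
  out <- list()
  for (r in seq_len(replicates)) {
    st <- do.call(sim2_study, c(list(seed = seeds[r]), sim))
    gv <- genetic_values(st$pop, st$arch)
    X <- genotypes(st$pop)[, st$markers, drop = FALSE]
    fam <- st$pop$ped$family
    s2 <- seeds[replicates + r]

    ph <- simulate_phenotypes(gv$tbv, h2 = 0.1, seed = s2 + 100)
    res <- cross_validate(ph$phenotype, X, "BayesB",
                          cv_scheme(5, 1, seed = s2), truth = gv$tbv,
                          families = fam, hyper = bench_hyper(s2))
    out[[length(out) + 1]] <- data.frame(
      replicate = r, n_families = 20, h2 = 0.1, method = "BayesB",
      accuracy = res$accuracy)

    keep <- fam %in% 1:5
    for (h2 in h2_grid) {
      ph <- simulate_phenotypes(gv$tbv[keep], h2 = h2,
                                seed = s2 + round(1000 * h2))
      res <- cross_validate(ph$phenotype, X[keep, , drop = FALSE],
                            c("G-BLUP", "BayesA", "BayesB"),
                            cv_scheme(5, 1, seed = s2),
                            truth = gv$tbv[keep], families = fam[keep],
                            hyper = bench_hyper(s2))
      sm <- res
      out[[length(out) + 1]] <- data.frame(
        replicate = r, n_families = 5, h2 = h2, method = sm$method,
        accuracy = sm$accuracy)
    }
  }
  do.call(rbind, out)
}

#' Replicated dominance comparison (family-based design)
#'
#' For each replicate, builds a 5-family study whose trait carries dominance
#' effects, then phenotypes the same genotypes twice: additive-only at
#' `h2 = 0.3`, and additive `h2 = 0.3` plus a dominance share of 0.3 (the
#' residual share drops from 0.7 to 0.4). BayesA and BayesB are evaluated by
#' five-fold CV against the additive TBV in both arms; the relative accuracy
#' decrease of the dominance arm is the quantity of interest.
#'
#' @param seed master seed.
#' @param replicates number of replicates.
#' @param h2 additive heritability (default 0.3).
#' @param dominance_share phenotypic variance share of dominance (0.3).
#' @param sim overrides passed to [sim2_study()].
#' @return long data.frame: replicate, arm ("additive"/"dominance"), method,
#'   accuracy.
#' @export
benchmark_sim3 <- function(seed, replicates = 10, h2 = 0.3,
                           dominance_share = 0.3, sim = list()) {
  seeds <- derive_seeds((seed %% 1000000000L) + 2L, replicates * 2)
  out <- list()
  for (r in seq_len(replicates)) {
    st <- do.call(sim2_study,
                  c(list(n_families = 5, family_size = 50,
                         dominance_ratio = dominance_share,
                         seed = seeds[r]), sim))
    gv <- genetic_values(st$pop, st$arch)
    X <- genotypes(st$pop)[, st$markers, drop = FALSE]
    fam <- st$pop$ped$family
    s2 <- seeds[replicates + r]
    arms <- list(additive = simulate_phenotypes(gv$tbv, h2 = h2,
                                                seed = s2 + 1),
                 dominance = simulate_phenotypes(gv$tbv, gv$dominance,
                                                 h2 = h2,
                                                 dominance_share = dominance_share,
                                                 seed = s2 + 2))
    for (arm in names(arms)) {
      res <- cross_validate(arms[[arm]]$phenotype, X,
                            c("BayesA", "BayesB"),
                            cv_scheme(5, 1, seed = s2), truth = gv$tbv,
                            families = fam, hyper = bench_hyper(s2))
      out[[length(out) + 1]] <- data.frame(
        replicate = r, arm = arm, method = res$method,
        accuracy = res$accuracy)
    }
  }
  do.call(rbind, out)
}
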