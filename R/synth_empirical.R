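# Synthetic stand-in for the five-family empirical scallop dataset. The real
# genotypes are not publicly available, so this generator emulates the
# dataset's published structure: 349 individuals in two full-sib and three
# bi-parental families, 2,364 polymorphic SNPs (MAF > 5%) with a mean call
# rate of 84%, and three correlated growth traits (shell length, width and
# height) with family-specific means and medium heritabilities. Every file
# or object derived from it is synthetic and is labelled as such.

#' Generate the synthetic five-family empirical-style dataset
#'
#' Two diverged sub-populations are produced by a shared Fisher-Wright
#' burn-in followed by independent drift; the two "full-sib" families draw
#' their parents from one sub-population and the three "bi-parental"
#' families from the other, which reproduces the observed genotype
#' structure (the two groups separate in a genotype PCA). Trait loci are
#' drawn from the genotyped marker set with effects correlated across the
#' three traits; family-specific phenotype offsets are large enough for a
#' one-way ANOVA to separate families, and the residual variance of each
#' trait is calibrated against the within-family additive variance to hit
#' the target across-family heritabilities. Genotypes are masked missing
#' completely at random at `1 - call_rate`.
#'
#' @param config optional list of overrides:
#'   \describe{
#'     \item{n_per_family}{family sizes (default 72, 70, 70, 69, 68 = 349).}
#'     \item{n_markers}{marker count (default 2364).}
#'     \item{h2}{named target heritabilities (default SL = 0.48, SW = 0.36,
#'       SH = 0.48).}
#'     \item{call_rate}{mean genotype call rate (default 0.84).}
#'     \item{trait_cor}{genetic correlation between traits (default 0.6).}
#'     \item{n_qtl}{trait loci per trait (default 300).}
#'     \item{trait_means}{baseline trait means, mm (default SL = 95,
#'       SW = 22, SH = 93).}
#'     \item{family_spread}{scale of family offsets in within-family
#'       phenotypic SDs (default 1.0).}
#'     \item{divergence_gen}{generations of independent drift between the
#'       two parent sub-populations (default 40).}
#'   }
#' @param seed integer seed.
#' @return list with `genotypes` (349 x n_markers matrix, 0/1/2 with NA),
#'   `phenotypes` (data.frame id, family, group, SL, SW, SH), `tbv` (matrix
#'   of true additive values per trait), `map` (marker map), `h2_target`.
#' @export
synth_empirical_dataset <- function(config = list(), seed = NULL) {
  cfg <- utils::modifyList(list(
    n_per_family = c(72, 70, 70, 69, 68),
    n_markers = 2364,
    h2 = c(SL = 0.48, SW = 0.36, SH = 0.48),
    call_rate = 0.84,
    trait_cor = 0.6,
    n_qtl = 300,
    trait_means = c(SL = 95, SW = 22, SH = 93),
    family_spread = 1.0,
    divergence_gen = 40,
    burnin_n = 120,
    burnin_gen = 150,
    n_chrom = 19, chrom_cm = 60
  ), config)
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), 10)
  n_fam <- length(cfg$n_per_family)
  traits <- names(cfg$h2)

  n_loci <- round(cfg$n_markers * 2.5)
  map <- marker_map(n_loci, cfg$n_chrom, cfg$chrom_cm, seed = seeds[1])
  base <- founder_population(map, cfg$burnin_n, seed = seeds[2])
  base <- burnin_fisher_wright(base, cfg$burnin_gen, seed = seeds[3])

  # two diverged parent sub-populations (full-sib group vs bi-parental group)
  half <- cfg$burnin_n / 2
  split_pop <- function(rows, label, sd_) {
    sub <- new_population(base$loci,
                          base$H1[rows, , drop = FALSE],
                          base$H2[rows, , drop = FALSE],
                          within(base$ped[rows, ], id <- paste0(label, seq_along(rows))),
                          base$generation)
    burnin_fisher_wright(sub, cfg$divergence_gen, pop_size = length(rows),
                         seed = sd_)
  }
  popA <- split_pop(seq_len(half), "A", seeds[4])
  popB <- split_pop(half + seq_len(half), "B", seeds[5])

  fams <- with_seed(seeds[6], {
    lapply(seq_len(n_fam), function(f) {
      src <- if (f <= 2) popA else popB
      males <- which(src$ped$sex == "M"); females <- which(src$ped$sex == "F")
      sire <- sample(males, 1); dam <- sample(females, 1)
      n_off <- cfg$n_per_family[f]
      P1 <- t(src$H1); P2 <- t(src$H2)
      H1 <- t(drop_gametes_cpp(P1, P2, rep(as.integer(sire), n_off),
                               0, src$loci$cm / 100, as.integer(src$loci$chrom)))
      H2 <- t(drop_gametes_cpp(P1, P2, rep(as.integer(dam), n_off),
                               0, src$loci$cm / 100, as.integer(src$loci$chrom)))
      list(H1 = H1, H2 = H2, family = f,
           group = if (f <= 2) "full-sib" else "bi-parental")
    })
  })
  H1 <- do.call(rbind, lapply(fams, `[[`, "H1"))
  H2 <- do.call(rbind, lapply(fams, `[[`, "H2"))
  family <- rep(seq_len(n_fam), cfg$n_per_family)
  group <- rep(vapply(fams, `[[`, character(1), "group"), cfg$n_per_family)
  n <- nrow(H1)
  ids <- sprintf("S%03d", seq_len(n))
  Xall <- H1 + H2

  maf <- maf_of(Xall)
  poly <- which(maf > 0.05)
  assert_that(length(poly) >= cfg$n_markers,
              "not enough polymorphic loci; increase the locus surplus")
  markers <- with_seed(seeds[7], sort(sample(poly, cfg$n_markers)))
  X <- Xall[, markers, drop = FALSE]
  dimnames(X) <- list(ids, map$id[markers])

  # correlated trait architectures drawn from the genotyped markers
  tbv <- with_seed(seeds[8], {
    qtl <- sample(seq_len(ncol(X)), cfg$n_qtl)
    R <- matrix(cfg$trait_cor, length(traits), length(traits))
    diag(R) <- 1
    Lc <- chol(R)
    eff <- matrix(rnorm(cfg$n_qtl * length(traits)), cfg$n_qtl) %*% Lc
    out <- X[, qtl, drop = FALSE] %*% eff
    colnames(out) <- traits
    out
  })

  # Residual variances are calibrated against the estimator the published
  # heritabilities come from: REML with the marker-based relationship matrix
  # and family fixed effects. A pilot phenotype gives the REML scale of the
  # genetic variance, from which the residual variance hitting the target h2
  # is solved; the final error term is then drawn at that variance.
  Xmiss <- with_seed(seeds[10], {
    M <- X
    storage.mode(M) <- "double"
    M[runif(length(M)) > cfg$call_rate] <- NA_real_
    M
  })
  # calibrate against the matrix the analyst will see: masked then imputed
  G_full <- genomic_relationship_matrix(impute_mean(Xmiss))
  W_fam <- stats::model.matrix(~factor(family))
  phen <- with_seed(seeds[9], {
    out <- data.frame(id = ids, family = family, group = group)
    for (t in traits) {
      g <- tbv[, t]
      g_w <- g - ave(g, family)           # within-family additive deviation
      var_aw <- var(g_w)
      h2 <- cfg$h2[[t]]
      var_e <- var_aw * (1 - h2) / h2
      z <- rnorm(n) # fixed error shape; only its scale is calibrated
      for (it in 1:4) {
        pilot <- estimate_h2_reml(g_w + z * sqrt(var_e), G_full, W_fam)
        # rescale the residual by the ratio of the achieved to the target
        # variance ratio (fixed-point step on the REML estimate)
        ratio <- (pilot$sigma_e2 / pilot$sigma_a2) /
          ((1 - h2) / h2)
        var_e <- max(var_e / ratio, 0.02 * var_aw)
        if (abs(log(ratio)) < 0.05) break
      }
      offsets <- rnorm(n_fam, 0, cfg$family_spread * sqrt(var_aw / h2))
      y <- cfg$trait_means[[t]] + offsets[family] + g_w + z * sqrt(var_e)
      out[[t]] <- round(y, 1)
    }
    out
  })

  list(genotypes = Xmiss, phenotypes = phen, tbv = tbv,
       map = map[markers, ], h2_target = cfg$h2)
}
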