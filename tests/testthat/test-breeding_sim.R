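# Fisher-Wright burn-in, meiosis, mating designs, trait architectures and
# phenotype calibration.

test_that("burn-in preserves the population contract", {
  map <- marker_map(50, 3, 50, seed = 1)
  base <- founder_population(map, 40, seed = 2)
  expect_identical(burnin_fisher_wright(base, 0), base)
  expect_error(burnin_fisher_wright(base, 10, pop_size = 0), "positive")
  expect_error(burnin_fisher_wright(base, 10, pop_size = 41), "even")
  b1 <- burnin_fisher_wright(base, 25, seed = 5)
  b2 <- burnin_fisher_wright(base, 25, seed = 5)
  expect_identical(b1$H1, b2$H1)
  expect_identical(b1$H2, b2$H2)
  expect_equal(dim(b1$H1), dim(base$H1))
})

test_that("drift decays heterozygosity at the closed-form rate", {
  # single locus, p0 = 0.5, N = 50, no mutation, t = 20:
  # E[2p(1-p)] = 0.5 * (1 - 1/(2N))^t
  N <- 50; t <- 20; reps <- 400
  map <- data.frame(id = "L1", chrom = 1L, pos = 0L, cm = 0, freq = 0.5)
  set.seed(42)
  het <- vapply(seq_len(reps), function(i) {
    base <- founder_population(map, N)
    b <- burnin_fisher_wright(base, t, mutation_rate = 0)
    p <- mean(b$H1 + b$H2) / 2
    2 * p * (1 - p)
  }, numeric(1))
  expected <- 0.5 * (1 - 1 / (2 * N))^t
  se <- sd(het) / sqrt(reps)
  expect_lt(abs(mean(het) - expected), 4 * se + 0.005)
})

test_that("neutral fixation probability matches the initial frequency", {
  N <- 24; reps <- 300; p0 <- 0.3
  map <- data.frame(id = "L1", chrom = 1L, pos = 0L, cm = 0, freq = p0)
  set.seed(43)
  fixed_alt <- 0; fixed_any <- 0
  for (i in seq_len(reps)) {
    base <- founder_population(map, N)
    b <- burnin_fisher_wright(base, 300, mutation_rate = 0)
    p <- mean(b$H1 + b$H2) / 2
    if (p == 0 || p == 1) {
      fixed_any <- fixed_any + 1
      if (p == 1) fixed_alt <- fixed_alt + 1
    }
  }
  expect_gt(fixed_any / reps, 0.95) # essentially all runs fixed by t = 12N
  phat <- fixed_alt / fixed_any
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / fixed_any))
})

test_that("gametes are parental mosaics with Haldane recombination", {
  # identical parental haplotypes pass through unchanged
  map <- marker_map(30, 2, 50, seed = 3)
  H <- matrix(rbinom(30, 1, 0.5), 1)
  storage.mode(H) <- "integer"
  pop <- radgs:::new_population(map, H, H,
                                data.frame(id = "P1", sire = NA, dam = NA,
                                           family = NA, generation = "G0",
                                           sex = "M"))
  g <- make_gamete(pop, 1, seed = 9)
  expect_identical(g, drop(H))

  # two loci 50 cM apart: recombinant fraction 0.5 * (1 - exp(-1)) = 0.3161
  map2 <- data.frame(id = c("a", "b"), chrom = 1L, pos = c(0L, 5e5L),
                     cm = c(0, 50), freq = 0.5)
  pop2 <- radgs:::new_population(
    map2, matrix(c(0L, 0L), 1), matrix(c(1L, 1L), 1),
    data.frame(id = "P1", sire = NA, dam = NA, family = NA,
               generation = "G0", sex = "M"))
  set.seed(10)
  n <- 10000
  gam <- drop_gametes_cpp(t(pop2$H1), t(pop2$H2), rep(1L, n), 0,
                          map2$cm / 100, map2$chrom)
  rec <- mean(gam[1, ] != gam[2, ])
  r_exp <- 0.5 * (1 - exp(-2 * 0.5))
  expect_lt(abs(rec - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n))
  # single-locus transmission is fair
  expect_lt(abs(mean(gam[1, ]) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("mating designs produce the stated family structures", {
  map <- marker_map(60, 3, 40, seed = 4)
  base <- burnin_fisher_wright(founder_population(map, 500, seed = 5), 5,
                               seed = 6)
  # paired design: 100 x 100 parents, 20 offspring/pair -> 2,000 offspring
  g1 <- mate_design(base, n_families = 100, family_size = 20, seed = 7)
  expect_equal(nrow(g1$H1), 2000)
  expect_equal(as.vector(table(g1$ped$family)), rep(20L, 100))
  expect_equal(length(unique(paste(g1$ped$sire, g1$ped$dam))), 100)
  expect_equal(length(unique(g1$ped$sire)), 100)

  # family design: 10 males x 10 females -> 20 families x 50
  g2 <- mate_design(base, n_families = 20, family_size = 50,
                    n_sires = 10, n_dams = 10, seed = 8)
  expect_equal(nrow(g2$H1), 1000)
  expect_equal(length(unique(g2$ped$sire)), 10)
  expect_equal(length(unique(g2$ped$dam)), 10)
  expect_equal(length(unique(paste(g2$ped$sire, g2$ped$dam))), 20)
  expect_equal(max(table(g2$ped$sire)) / 50, 2) # each sire in two matings

  expect_error(mate_design(base, n_families = 600, family_size = 2,
                           n_sires = 400, n_dams = 400), "not enough")
})

test_that("offspring alleles are Mendelian-consistent with their parents", {
  map <- marker_map(200, 4, 50, seed = 11)
  base <- burnin_fisher_wright(founder_population(map, 60, seed = 12), 30,
                               seed = 13)
  off <- mate_design(base, n_families = 6, family_size = 10,
                     n_sires = 3, n_dams = 3, seed = 14)
  for (i in seq_len(nrow(off$H1))) {
    s <- match(off$ped$sire[i], base$ped$id)
    d <- match(off$ped$dam[i], base$ped$id)
    # haplotype 1 from sire: allele present on one of the sire's haplotypes
    expect_true(all(off$H1[i, ] == base$H1[s, ] | off$H1[i, ] == base$H2[s, ]))
    expect_true(all(off$H2[i, ] == base$H1[d, ] | off$H2[i, ] == base$H2[d, ]))
  }
})

test_that("allele frequencies are conserved in expectation over one generation", {
  map <- marker_map(300, 5, 40, seed = 15)
  base <- burnin_fisher_wright(founder_population(map, 200, seed = 16), 10,
                               seed = 17)
  p0 <- colMeans(base$H1 + base$H2) / 2
  set.seed(18)
  drift <- replicate(30, {
    b <- burnin_fisher_wright(base, 1, mutation_rate = 0)
    mean(colMeans(b$H1 + b$H2) / 2 - p0)
  })
  expect_lt(abs(mean(drift)), 3 * sd(drift) / sqrt(length(drift)) + 1e-4)
})

test_that("assign_qtl draws standard normal effects on unique loci", {
  a <- assign_qtl(10000, 5000, seed = 21)
  expect_length(unique(a$qtl), 5000)
  expect_lt(abs(mean(a$a)), 3 / sqrt(5000))
  expect_lt(abs(var(a$a) - 1), 0.1)
  expect_true(all(a$d == 0))
  ad <- assign_qtl(100, 10, dominance_ratio = 0.3, seed = 22)
  expect_true(any(ad$d != 0))
  expect_error(assign_qtl(10, 11), "n_qtl")
})

test_that("genetic values match a naive per-individual summation", {
  td <- toy_family_data(seed = 301, n_families = 4, family_size = 15,
                        burnin_gen = 50)
  pop <- td$pop; arch <- td$arch
  gv <- genetic_values(pop, arch)
  G <- pop$H1 + pop$H2
  idx <- sample(nrow(G), 50)
  for (i in idx) {
    tbv_i <- sum(G[i, arch$qtl] * arch$a)
    expect_equal(gv$tbv[i], tbv_i, tolerance = 1e-12)
  }
  # all-homozygous-reference individual has TBV 0
  z <- pop
  z$H1[1, ] <- 0L; z$H2[1, ] <- 0L
  expect_equal(genetic_values(z, arch)$tbv[1], 0)
  # a single heterozygous QTL contributes a_1 and d_1
  arch1 <- structure(list(qtl = arch$qtl[1], a = 2.5, d = 0.7,
                          dominance_ratio = 0.3),
                     class = "trait_architecture")
  z$H1[1, arch$qtl[1]] <- 1L
  gv1 <- genetic_values(z, arch1)
  expect_equal(gv1$tbv[1], 2.5)
  expect_equal(gv1$dominance[1], 0.7)
})

test_that("phenotype error calibration recovers the target heritability", {
  set.seed(31)
  tbv <- rnorm(10000, 0, 3)
  ph <- simulate_phenotypes(tbv, h2 = 0.5, seed = 32)
  expect_lt(abs(attr(ph, "realized_h2") - 0.5), 0.03)
  # h2 = 1: phenotype equals the genetic value exactly
  ph1 <- simulate_phenotypes(tbv, h2 = 1, seed = 33)
  expect_identical(ph1$phenotype, tbv)
  # reproducibility
  expect_identical(simulate_phenotypes(tbv, h2 = 0.3, seed = 34)$phenotype,
                   simulate_phenotypes(tbv, h2 = 0.3, seed = 34)$phenotype)
  expect_error(simulate_phenotypes(rep(1, 10), h2 = 0.5), "variance")
  expect_error(simulate_phenotypes(tbv, h2 = 0), "h2")
})

test_that("dominance share is realized at the configured ratio", {
  set.seed(35)
  tbv <- rnorm(5000, 0, 2)
  dom <- rnorm(5000, 0, 5)
  ph <- simulate_phenotypes(tbv, dom, h2 = 0.3, dominance_share = 0.3,
                            seed = 36)
  vc <- attr(ph, "var_components")
  expect_lt(abs(vc[["var_d"]] / var(ph$phenotype) - 0.3), 0.05)
  expect_lt(abs(var(tbv) / var(ph$phenotype) - 0.3), 0.05)
})
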