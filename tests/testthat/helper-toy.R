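# Shared fixtures built in code: small populations and design objects used
# across test files. Everything is seeded and cheap.

# A small family-structured dataset with known trait architecture.
toy_family_data <- function(seed = 101, n_families = 6, family_size = 25,
                            n_loci = 400, n_qtl = 60, h2 = 0.4,
                            burnin_gen = 150, burnin_n = 100) {
  seeds <- derive_seeds(seed, 6)
  map <- marker_map(n_loci, n_chrom = 5, chrom_cm = 40, seed = seeds[1])
  base <- founder_population(map, burnin_n, seed = seeds[2])
  base <- burnin_fisher_wright(base, burnin_gen, seed = seeds[3])
  pop <- mate_design(base, n_families = n_families, family_size = family_size,
                     n_sires = max(2, n_families %/% 2),
                     n_dams = max(2, n_families %/% 2), seed = seeds[4])
  X <- genotypes(pop)
  maf <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
  arch <- with_seed(seeds[5], {
    poly <- which(maf > 0)
    qtl <- sort(sample(poly, min(n_qtl, length(poly))))
    a <- assign_qtl(n_loci, length(qtl))
    a$qtl <- qtl
    a
  })
  gv <- genetic_values(pop, arch)
  ph <- simulate_phenotypes(gv$tbv, h2 = h2, seed = seeds[6])
  markers <- setdiff(which(maf > 0.05), arch$qtl)
  list(pop = pop, arch = arch, tbv = gv$tbv, dominance = gv$dominance,
       y = ph$phenotype, X = X[, markers, drop = FALSE],
       families = pop$ped$family)
}

toy_gs_data <- function(seed = 101, ...) {
  td <- toy_family_data(seed, ...)
  gs_data(td$y, td$X, families = td$families, tbv = td$tbv)
}

# Independent genotype simulator (no linkage machinery): HWE genotypes.
hwe_genotypes <- function(n, p_vec, seed = 1) {
  with_seed(seed, {
    X <- matrix(rbinom(n * length(p_vec), 2, rep(p_vec, each = n)), n)
    storage.mode(X) <- "double"
    X
  })
}

with_seed <- radgs:::with_seed
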