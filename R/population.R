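# Diploid populations: founders, Fisher-Wright burn-in, gametes and mating
# designs. Haplotypes are stored as two n x L integer matrices of alternate
# allele counts (0/1); loci are sorted by (chromosome, position).

#' Construct a locus map without an explicit genome sequence
#'
#' For family-scale designs the nucleotide sequence is irrelevant: only the
#' genetic map positions of the tracked loci matter. This helper places
#' `n_loci` loci uniformly at random over `n_chrom` chromosomes of the given
#' map length and assigns initial alternate-allele frequencies.
#'
#' @param n_loci total number of loci.
#' @param n_chrom number of chromosomes.
#' @param chrom_cm genetic length of each chromosome in centimorgans.
#' @param freq_model (min, max) of the uniform initial-frequency spectrum.
#' @param seed optional integer seed.
#' @return a data.frame with columns `id`, `chrom`, `pos`, `cm`, `freq`,
#'   sorted by (chrom, cm). `pos` is a pseudo base-pair position at 1 Mb/cM.
#' @export
marker_map <- function(n_loci, n_chrom = 19, chrom_cm = 60,
                       freq_model = c(0.05, 0.95), seed = NULL) {
  assert_that(n_loci >= 1 && n_chrom >= 1 && chrom_cm > 0, "invalid map spec")
  with_seed(seed, {
    chrom <- sort(sample.int(n_chrom, n_loci, replace = TRUE))
    cm <- runif(n_loci, 0, chrom_cm)
    ord <- order(chrom, cm)
    chrom <- chrom[ord]; cm <- cm[ord]
    data.frame(id = paste0("L", seq_len(n_loci)),
               chrom = chrom,
               pos = as.integer(round(cm * 1e6 / 1)),
               cm = cm,
               freq = runif(n_loci, freq_model[1], freq_model[2]))
  })
}

# Locus table from a SNP catalogue subset (tracked loci), cm via a constant
# cM/Mb rate.
loci_from_catalogue <- function(snps, idx, cm_per_mb = 1) {
  idx <- sort(unique(idx))
  data.frame(id = paste0(snps$chrom[idx], ":", snps$pos[idx]),
             chrom = match(snps$chrom[idx], unique(snps$chrom)),
             pos = snps$pos[idx],
             cm = snps$pos[idx] / 1e6 * cm_per_mb,
             freq = snps$freq[idx],
             catalogue_index = idx)
}

new_population <- function(loci, H1, H2, ped, generation = "G0") {
  stopifnot(nrow(H1) == nrow(H2), ncol(H1) == nrow(loci),
            nrow(ped) == nrow(H1), !anyDuplicated(ped$id))
  structure(list(loci = loci, H1 = H1, H2 = H2, ped = ped,
                 generation = generation),
            class = "gs_population")
}

#' @export
print.gs_population <- function(x, ...) {
  cat(sprintf("Population %s: %d individuals x %d loci, %d famil%s\n",
              x$generation, nrow(x$H1), ncol(x$H1),
              length(unique(x$ped$family[!is.na(x$ped$family)])),
              if (length(unique(x$ped$family[!is.na(x$ped$family)])) == 1) "y" else "ies"))
  invisible(x)
}

#' Create a founder population from a locus map
#'
#' Founder haplotype alleles are drawn independently as Bernoulli(initial
#' frequency) per locus, i.e. linkage equilibrium; linkage disequilibrium is
#' generated subsequently by drift during burn-in.
#'
#' @param loci locus table from [marker_map()] or [loci_from_catalogue()]
#'   (columns `chrom`, `cm`, `freq`).
#' @param n number of diploid founders.
#' @param seed optional integer seed.
#' @return a `gs_population`.
#' @export
founder_population <- function(loci, n, seed = NULL) {
  assert_that(n >= 2, "need at least 2 founders")
  L <- nrow(loci)
  with_seed(seed, {
    draw <- function() {
      m <- matrix(rbinom(n * L, 1L, rep(loci$freq, each = n)), nrow = n)
      storage.mode(m) <- "integer"
      m
    }
    ped <- data.frame(id = paste0("F", seq_len(n)),
                      sire = NA_character_, dam = NA_character_,
                      family = NA_integer_, generation = "G0",
                      sex = sample(c("M", "F"), n, replace = TRUE))
    new_population(loci, draw(), draw(), ped, "G0")
  })
}

#' Fisher-Wright neutral burn-in
#'
#' Evolves a population for `n_generations` of discrete non-overlapping
#' generations: each offspring is formed by sampling two parents uniformly
#' with replacement, gamete formation with Poisson-distributed crossovers on
#' the genetic map (Haldane model, no interference) and symmetric bi-allelic
#' mutation at `mutation_rate` per locus per gamete. Loci that drift to
#' fixation are retained. Sexes are (re)assigned i.i.d. at the end.
#'
#' @param pop a `gs_population` of founders.
#' @param n_generations number of generations (>= 0).
#' @param pop_size population size per generation (even); defaults to the
#'   founder count. If different, founders are resampled with replacement.
#' @param mutation_rate per-locus per-gamete mutation probability.
#' @param seed optional integer seed.
#' @return the evolved `gs_population` (generation label `G<n>`); pedigree
#'   links within the burn-in are not recorded.
#' @export
burnin_fisher_wright <- function(pop, n_generations, pop_size = NULL,
                                 mutation_rate = 1e-5, seed = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  pop_size <- pop_size %||% nrow(pop$H1)
  assert_that(pop_size > 0, "pop_size must be positive")
  assert_that(pop_size %% 2 == 0, "pop_size must be even")
  assert_that(n_generations >= 0, "n_generations must be >= 0")
  if (n_generations == 0) return(pop)
  with_seed(seed, {
    H1 <- pop$H1; H2 <- pop$H2
    if (pop_size != nrow(H1)) {
      pick <- sample.int(nrow(H1), pop_size, replace = TRUE)
      H1 <- H1[pick, , drop = FALSE]; H2 <- H2[pick, , drop = FALSE]
    }
    res <- wf_burnin_cpp(t(H1), t(H2), as.integer(n_generations),
                         mutation_rate, pop$loci$cm / 100,
                         as.integer(pop$loci$chrom))
    ped <- data.frame(id = paste0("B", seq_len(pop_size)),
                      sire = NA_character_, dam = NA_character_,
                      family = NA_integer_,
                      generation = paste0("G", n_generations),
                      sex = sample(c("M", "F"), pop_size, replace = TRUE))
    new_population(pop$loci, t(res$H1), t(res$H2), ped,
                   paste0("G", n_generations))
  })
}

#' Form one gamete from a parent
#'
#' Crossover counts per chromosome are Poisson with mean equal to the map
#' length in Morgans (Haldane); chromosomes assort independently.
#'
#' @param pop a `gs_population`.
#' @param parent id or row index of the parent.
#' @param mutation_rate per-locus mutation probability (default 0).
#' @param seed optional integer seed.
#' @return integer haplotype vector of length `n_loci`.
#' @export
make_gamete <- function(pop, parent, mutation_rate = 0, seed = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  if (is.character(parent)) parent <- match(parent, pop$ped$id)
  assert_that(!is.na(parent) && parent >= 1 && parent <= nrow(pop$H1),
              "unknown parent")
  with_seed(seed, {
    drop_gametes_cpp(t(pop$H1), t(pop$H2), as.integer(parent), mutation_rate,
                     pop$loci$cm / 100, as.integer(pop$loci$chrom))[, 1]
  })
}

#' Apply a mating design to a population
#'
#' Selects sires and dams among the males and females of `pop`, forms
#' full-sib families and generates offspring by meiosis. Two stock designs
#' cover the simulated breeding schemes: a paired design (e.g. 100 sires x
#' 100 dams mated in distinct pairs, 20 offspring each) and a family design
#' in which a smaller parent pool is reused across families (e.g. 10 males
#' and 10 females producing 20 full-sib families of 50, each parent entering
#' two matings).
#'
#' @param pop parent `gs_population` with recorded sexes.
#' @param n_families number of full-sib families.
#' @param family_size offspring per family.
#' @param n_sires,n_dams sizes of the sire/dam pools (default `n_families`
#'   each, i.e. distinct pairs). Parents are reused round-robin when the pool
#'   is smaller than `n_families`; no pair is repeated.
#' @param generation label for the offspring generation.
#' @param mutation_rate per-locus mutation probability during meiosis.
#' @param seed optional integer seed.
#' @return offspring `gs_population` with pedigree (sire/dam ids referring to
#'   `pop`), family labels 1..n_families and random sexes.
#' @export
mate_design <- function(pop, n_families, family_size,
                        n_sires = n_families, n_dams = n_families,
                        generation = "G1", mutation_rate = 0, seed = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  males <- which(pop$ped$sex == "M")
  females <- which(pop$ped$sex == "F")
  assert_that(length(males) >= n_sires && length(females) >= n_dams,
              sprintf("not enough parents: %d males / %d females available, %d / %d required",
                      length(males), length(females), n_sires, n_dams))
  assert_that(n_sires <= n_families && n_dams <= n_families,
              "parent pools cannot exceed the number of families")
  with_seed(seed, {
    sires <- sample(males, n_sires)
    dams <- sample(females, n_dams)
    # round-robin with a per-cycle shift so no (sire, dam) pair repeats
    fam_sire <- sires[(seq_len(n_families) - 1L) %% n_sires + 1L]
    shift <- (seq_len(n_families) - 1L) %/% n_sires
    fam_dam <- dams[((seq_len(n_families) - 1L + shift) %% n_dams) + 1L]

    n_off <- n_families * family_size
    fam <- rep(seq_len(n_families), each = family_size)
    sire_vec <- fam_sire[fam]
    dam_vec <- fam_dam[fam]
    cm_m <- pop$loci$cm / 100
    chr <- as.integer(pop$loci$chrom)
    P1 <- t(pop$H1); P2 <- t(pop$H2)
    H1 <- t(drop_gametes_cpp(P1, P2, as.integer(sire_vec),
                             mutation_rate, cm_m, chr))
    H2 <- t(drop_gametes_cpp(P1, P2, as.integer(dam_vec),
                             mutation_rate, cm_m, chr))
    ped <- data.frame(id = paste0(generation, "_", seq_len(n_off)),
                      sire = pop$ped$id[sire_vec],
                      dam = pop$ped$id[dam_vec],
                      family = fam, generation = generation,
                      sex = sample(c("M", "F"), n_off, replace = TRUE))
    new_population(pop$loci, H1, H2, ped, generation)
  })
}

#' Genotype matrix of a population
#'
#' @param pop a `gs_population`.
#' @return integer matrix (individuals x loci) of alternate-allele counts
#'   0/1/2, with individual ids as row names and locus ids as column names.
#' @export
genotypes <- function(pop) {
  stopifnot(inherits(pop, "gs_population"))
  X <- pop$H1 + pop$H2
  dimnames(X) <- list(pop$ped$id, pop$loci$id)
  X
}
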