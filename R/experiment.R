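# Study scenario builders tying the genome, tag, panel and breeding modules
# together, and the experiment orchestrator.
#
# Two construction routes are used, both desk-scale versions of the same
# study design:
#  * sim1_study(): explicit genome route. A sequence genome is simulated,
#    SNPs injected, BsaXI/RTR tags located and HD/MD/LD panels assembled at
#    the per-Mb densities of the full-scale design; a Fisher-Wright burn-in
#    then a 100x100 paired mating produces generations G1 and G2.
#  * sim2_study(): map-only route for family designs. Only the loci that are
#    actually tracked (markers + QTL candidates) are simulated, placed on a
#    genetic map; the nucleotide sequence is irrelevant at this stage.
# In both routes marker panels and QTLs are drawn among loci that are still
# polymorphic after burn-in, so panel sizes and QTL counts are the nominal
# ones at phenotyping time.

maf_of <- function(X) {
  p <- colMeans(X) / 2
  pmin(p, 1 - p)
}

sample_at_most <- function(x, size) {
  if (length(x) <= size) x else sort(sample(x, size))
}

#' Population-scale simulation study (genome route)
#'
#' Builds the population-based design: simulated genome, injected SNPs,
#' BsaXI/RTR tag discovery, HD/MD/LD marker panels at fixed per-Mb
#' densities, 1000-generation Fisher-Wright burn-in (N = 500 by default) and
#' two generations of 100 sire x 100 dam paired matings with 20
#' offspring/pair (G1, then G2 from G1). Panels and QTLs are drawn among
#' loci segregating in G1.
#'
#' @param genome_mb total genome size in Mb (desk-scale stand-in for a ~1 Gb
#'   genome; densities per Mb are preserved instead of absolute counts).
#' @param n_chrom number of chromosomes.
#' @param snp_rate per-base SNP injection rate.
#' @param panels which panels to track: subset of `c("HD", "MD", "LD")`.
#'   Tracking HD at 250/Mb is markedly more expensive.
#' @param hd_per_mb,md_per_mb,ld_per_mb target panel densities (markers/Mb).
#' @param qtl_per_mb QTL density (QTLs/Mb); ~5 QTL/Mb mirrors 5,000 QTLs on
#'   a ~1 Gb genome.
#' @param burnin_n,burnin_gen burn-in population size and generations.
#' @param mutation_rate per-locus per-gamete mutation rate during burn-in.
#' @param cm_per_mb genetic map density.
#' @param n_pairs,offspring_per_pair mating design (100 x 20 = 2,000).
#' @param surplus tracking surplus factor: the burn-in tracks `surplus`
#'   times more candidate loci than each panel needs, so panels can be
#'   filled with polymorphic loci after drift.
#' @param seed integer master seed.
#' @return list with `G1`, `G2` (populations), `panels` (named list of
#'   tracked-locus index vectors), `arch` (trait architecture on tracked
#'   loci), `genome_mb`, `tag_counts`.
#' @export
sim1_study <- function(genome_mb = 20, n_chrom = 10, snp_rate = 0.02,
                       panels = c("MD", "LD"),
                       hd_per_mb = 250, md_per_mb = 50, ld_per_mb = 5,
                       qtl_per_mb = 5, burnin_n = 500, burnin_gen = 1000,
                       mutation_rate = 1e-5, cm_per_mb = 1,
                       n_pairs = 100, offspring_per_pair = 20,
                       surplus = 2.5, seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), 8)
  chrom_len <- round(genome_mb * 1e6 / n_chrom)
  genome <- simulate_genome(n_chrom, chrom_len, seed = seeds[1])
  snps <- inject_snps(genome, snp_rate, seed = seeds[2])
  tags <- find_bsaxi_tags(genome)
  rtr <- rtr_filter(tags, genome)

  hd_n <- round(hd_per_mb * genome_mb)
  md_n <- round(md_per_mb * genome_mb)
  ld_n <- round(ld_per_mb * genome_mb)
  qtl_n <- round(qtl_per_mb * genome_mb)
  built <- build_marker_panels(
    snps, tags, rtr_tags = rtr,
    hd_size = if ("HD" %in% panels) min(round(hd_n * surplus), nrow(snps)) else 10,
    md_subsample = round(md_n * surplus),
    ld_subsample = round(ld_n * surplus),
    seed = seeds[3])
  panel_idx <- list(HD = built$HD$loci, MD = built$MD$loci, LD = built$LD$loci)
  panel_idx <- panel_idx[panels]
  qtl_cand <- with_seed(seeds[4], {
    pool <- setdiff(seq_len(nrow(snps)), unique(unlist(panel_idx)))
    sample_at_most(pool, round(qtl_n * surplus))
  })
  tracked <- sort(unique(c(unlist(panel_idx), qtl_cand)))
  loci <- loci_from_catalogue(snps, tracked, cm_per_mb)

  base <- founder_population(loci, burnin_n, seed = seeds[5])
  base <- burnin_fisher_wright(base, burnin_gen,
                               mutation_rate = mutation_rate,
                               seed = seeds[6])
  G1 <- mate_design(base, n_families = n_pairs,
                    family_size = offspring_per_pair,
                    generation = "G1", seed = seeds[7])
  G2 <- mate_design(G1, n_families = n_pairs,
                    family_size = offspring_per_pair,
                    generation = "G2", seed = seeds[8])

  maf1 <- maf_of(genotypes(G1))
  to_tracked <- function(catalogue_idx) match(catalogue_idx, tracked)
  pick_panel <- function(idx, target) {
    tr <- to_tracked(idx)
    poly <- tr[maf1[tr] >= 0.05]
    sample_at_most(poly, target)
  }
  panel_sizes <- c(HD = hd_n, MD = md_n, LD = ld_n)
  panel_final <- lapply(names(panel_idx), function(nm) {
    pick_panel(panel_idx[[nm]], panel_sizes[[nm]])
  })
  names(panel_final) <- names(panel_idx)
  qtl_tr <- to_tracked(qtl_cand)
  qtl_poly <- qtl_tr[maf1[qtl_tr] > 0]
  arch <- with_seed(seeds[4] + 1L, {
    chosen <- sample_at_most(qtl_poly, qtl_n)
    a <- assign_qtl(nrow(loci), length(chosen))
    a$qtl <- sort(chosen)
    a
  })
  list(G1 = G1, G2 = G2, panels = panel_final, arch = arch,
       genome_mb = genome_mb,
       tag_counts = c(bsaxi = nrow(tags), rtr = nrow(rtr)))
}

#' Family-scale simulation study (map route)
#'
#' Builds the family-based design: a marker map of tracked loci,
#' Fisher-Wright burn-in, then full-sib families produced by a small parent
#' pool (10 males x 10 females giving 20 families of 50 by default; each
#' parent enters two matings). The requested number of markers is drawn from
#' loci with MAF >= 0.05 among the offspring, QTLs from the remaining
#' segregating loci.
#'
#' @param n_families,family_size family design (20 x 50 by default).
#' @param n_sires,n_dams parent pool sizes.
#' @param n_markers marker panel size (2,364 mirrors the 2b-RAD subset).
#' @param n_qtl number of QTLs; the default matches the marker count, which
#'   preserves the full-scale design's QTL:marker ratio (~5 of each per Mb).
#' @param n_chrom,chrom_cm genetic map; the default 19 chromosomes of 25 cM
#'   give the map span over which 2,364 markers occur at ~5 markers/cM
#'   (1 cM/Mb), the low-density panel's density.
#' @param burnin_n,burnin_gen,mutation_rate burn-in settings.
#' @param surplus locus tracking surplus (see [sim1_study()]).
#' @param dominance_ratio target dominance share passed to [assign_qtl()]
#'   (draws raw dominance effects when positive).
#' @param seed integer master seed.
#' @return list with `pop` (offspring population), `parents`, `markers`
#'   (tracked-locus indices), `arch`.
#' @export
sim2_study <- function(n_families = 20, family_size = 50,
                       n_sires = min(10, n_families),
                       n_dams = min(10, n_families),
                       n_markers = 2364, n_qtl = n_markers,
                       n_chrom = 19, chrom_cm = 25,
                       burnin_n = 500, burnin_gen = 1000,
                       mutation_rate = 1e-5, surplus = 2.5,
                       dominance_ratio = 0, seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), 6)
  n_loci <- round((n_markers + n_qtl) * surplus)
  map <- marker_map(n_loci, n_chrom, chrom_cm, seed = seeds[1])
  base <- founder_population(map, burnin_n, seed = seeds[2])
  base <- burnin_fisher_wright(base, burnin_gen,
                               mutation_rate = mutation_rate,
                               seed = seeds[3])
  pop <- mate_design(base, n_families = n_families,
                     family_size = family_size,
                     n_sires = n_sires, n_dams = n_dams,
                     generation = "G1", seed = seeds[4])
  maf <- maf_of(genotypes(pop))
  poly <- which(maf >= 0.05)
  if (length(poly) < n_markers)
    warning(sprintf("only %d loci with MAF >= 0.05 available for %d markers",
                    length(poly), n_markers))
  markers <- with_seed(seeds[5], sample_at_most(poly, n_markers))
  qtl_pool <- setdiff(which(maf > 0), markers)
  arch <- with_seed(seeds[6], {
    chosen <- sample_at_most(qtl_pool, n_qtl)
    a <- assign_qtl(nrow(map), length(chosen),
                    dominance_ratio = dominance_ratio)
    a$qtl <- sort(chosen)
    a
  })
  list(pop = pop, parents = base, markers = markers, arch = arch)
}

#' Subset a family study to a set of families
#'
#' @param study result of [sim2_study()].
#' @param families family labels to keep (e.g. `1:5`).
#' @return the study with `pop` restricted to those families.
#' @export
subset_families <- function(study, families) {
  pop <- study$pop
  keep <- pop$ped$family %in% families
  study$pop <- new_population(pop$loci,
                              pop$H1[keep, , drop = FALSE],
                              pop$H2[keep, , drop = FALSE],
                              pop$ped[keep, , drop = FALSE],
                              pop$generation)
  study
}

#' Run a scenario grid and collect accuracy tables
#'
#' Orchestrates simulation, model fitting and evaluation over a grid of
#' heritabilities, marker panels (population design) or family counts
#' (family design) and methods, producing a long-format results table and a
#' per-cell summary, reproducible from the master seed.
#'
#' @param config nested list (or path to a YAML file readable by
#'   [read_run_config()]) with elements:
#'   \describe{
#'     \item{design}{"sim1", "sim2" or "sim3".}
#'     \item{h2}{vector of heritabilities.}
#'     \item{methods}{methods to fit.}
#'     \item{panels}{sim1 only: panels to evaluate.}
#'     \item{n_families}{sim2 only: vector of family counts (subsets of the
#'       full design).}
#'     \item{replicates}{number of independent simulation replicates.}
#'     \item{cv}{list(k, repeats) for the cross-validation scheme.}
#'     \item{hyper}{list of [gs_hyper()] overrides.}
#'     \item{scale}{list of overrides passed to the study builder.}
#'     \item{seed}{master seed.}
#'   }
#' @param outdir optional directory; when given, results, summary and a JSON
#'   manifest are written there.
#' @return list with `results` (long data.frame: replicate, scenario
#'   columns, method, rep, fold, accuracy, slope), `summary` (mean/SD per
#'   cell) and `manifest`.
#' @export
run_experiment <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  seeds <- derive_seeds(config$seed, config$replicates * 2 + 1)
  hyper <- do.call(gs_hyper, config$hyper)
  scheme <- cv_scheme(k = config$cv$k, repeats = config$cv$repeats)
  rows <- list()
  add <- function(df, ...) {
    meta <- data.frame(...)
    rows[[length(rows) + 1]] <<- cbind(meta[rep(1, nrow(df)), , drop = FALSE], df)
  }
  for (r in seq_len(config$replicates)) {
    sr <- seeds[2 * r - 1]
    if (config$design == "sim1") {
      study <- do.call(sim1_study,
                       c(list(panels = config$panels, seed = sr), config$scale))
      gv1 <- genetic_values(study$G1, study$arch)
      X1 <- genotypes(study$G1)
      for (h2 in config$h2) {
        ph <- simulate_phenotypes(gv1$tbv, h2 = h2, seed = seeds[2 * r] + round(1e3 * h2))
        for (pn in config$panels) {
          cols <- study$panels[[pn]]
          scheme$seed <- sr + 7L
          res <- cross_validate(ph$phenotype, X1[, cols, drop = FALSE],
                                config$methods, scheme, truth = gv1$tbv,
                                hyper = hyper)
          add(res, replicate = r, design = "sim1", panel = pn, h2 = h2)
        }
      }
    } else {
      dom <- config$design == "sim3"
      defaults <- if (dom) list(n_families = 5, family_size = 50,
                                dominance_ratio = 0.3) else list()
      study <- do.call(sim2_study,
                       c(defaults, list(seed = sr), config$scale))
      gv <- genetic_values(study$pop, study$arch)
      fam_counts <- config$n_families %||% length(unique(study$pop$ped$family))
      for (nf in fam_counts) {
        sub <- if (nf < length(unique(study$pop$ped$family)))
          subset_families(study, seq_len(nf)) else study
        keep <- study$pop$ped$family %in% seq_len(nf)
        X <- genotypes(sub$pop)[, study$markers, drop = FALSE]
        fams <- sub$pop$ped$family
        for (h2 in config$h2) {
          ph <- simulate_phenotypes(gv$tbv[keep],
                                    dominance = if (dom) gv$dominance[keep],
                                    h2 = h2,
                                    dominance_share = if (dom) config$dominance_share else 0,
                                    seed = seeds[2 * r] + round(1e3 * h2))
          scheme$seed <- sr + 7L
          res <- cross_validate(ph$phenotype, X, config$methods, scheme,
                                truth = gv$tbv[keep], families = fams,
                                hyper = hyper)
          add(res, replicate = r, design = config$design,
              n_families = nf, h2 = h2)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  cell_cols <- setdiff(names(results),
                       c("replicate", "rep", "fold", "accuracy", "slope", "r_y"))
  summary_df <- stats::aggregate(
    results[, c("accuracy", "slope")],
    by = results[cell_cols],
    FUN = function(v) mean(v, na.rm = TRUE))
  sd_df <- stats::aggregate(list(accuracy_sd = results$accuracy),
                            by = results[cell_cols],
                            FUN = function(v) sd(v, na.rm = TRUE))
  summary_df <- merge(summary_df, sd_df)
  manifest <- list(config = config, seed = config$seed,
                   package_version = as.character(utils::packageVersion("radgs")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(results, file.path(outdir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summary_df, file.path(outdir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(results = results, summary = summary_df, manifest = manifest)
}
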