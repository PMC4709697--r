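# Simulated reference genomes and SNP injection.

#' Simulate a diploidizable reference genome
#'
#' Generates i.i.d. nucleotide sequences for a configurable number of
#' chromosomes. The simulated genome stands in for a real draft assembly at
#' desk scale: marker and QTL counts downstream are expressed per Mb so that
#' densities, the quantity that matters for reduced-representation panels,
#' are preserved when the genome is scaled down.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param chrom_length length of each chromosome in bases (>= 1000). Either a
#'   single value recycled to all chromosomes or a vector of per-chromosome
#'   lengths.
#' @param base_composition probabilities for A, C, G, T (in that order).
#'   Normalised internally; must be non-negative with a positive sum.
#' @param seed optional integer seed; identical seeds give identical genomes.
#' @return an object of class `radgs_genome`: a list with `seq` (a named
#'   [Biostrings::DNAStringSet]), `base_composition` (target), and
#'   `realized_composition`.
#' @examples
#' g <- simulate_genome(2, 5e4, seed = 1)
#' g$realized_composition
#' @export
simulate_genome <- function(n_chromosomes, chrom_length,
                            base_composition = c(0.25, 0.25, 0.25, 0.25),
                            seed = NULL) {
  assert_that(n_chromosomes >= 1, "n_chromosomes must be >= 1")
  assert_that(all(chrom_length >= 1000), "chrom_length must be >= 1 kb")
  assert_that(length(base_composition) == 4 && all(is.finite(base_composition)) &&
                all(base_composition >= 0) && sum(base_composition) > 0,
              "base_composition must be 4 non-negative probabilities with positive sum")
  comp <- base_composition / sum(base_composition)
  lens <- as.integer(rep_len(chrom_length, n_chromosomes))
  codes <- utf8ToInt("ACGT")
  seqs <- with_seed(seed, {
    vapply(lens, function(L) {
      intToUtf8(codes[sample.int(4L, L, replace = TRUE, prob = comp)])
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(n_chromosomes))
  dss <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::alphabetFrequency(dss, baseOnly = TRUE)
  tot <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  structure(list(seq = dss,
                 base_composition = setNames(comp, c("A", "C", "G", "T")),
                 realized_composition = tot / sum(tot)),
            class = "radgs_genome")
}

#' @export
print.radgs_genome <- function(x, ...) {
  cat("Simulated genome:", length(x$seq), "chromosome(s),",
      format(sum(Biostrings::width(x$seq)), big.mark = ","), "bp total\n")
  cat("Realized base composition:",
      paste(names(x$realized_composition),
            sprintf("%.3f", x$realized_composition), collapse = " "), "\n")
  invisible(x)
}

genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome$seq), names(genome$seq))
}

#' Inject SNPs into a genome at a target density
#'
#' Each base becomes a SNP independently with probability `rate`; the
#' alternate allele is drawn uniformly from the three non-reference bases and
#' the initial alternate-allele frequency from `freq_model` (uniform by
#' default). Positions are 0-based.
#'
#' @param genome a `radgs_genome`.
#' @param rate per-base SNP probability in (0, 1); 0.02 mirrors a 2%
#'   polymorphism rate.
#' @param freq_model length-2 vector giving the (min, max) of the uniform
#'   initial-frequency spectrum.
#' @param seed optional integer seed.
#' @return a `snp_catalogue`: data.frame with columns `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `freq`, positions strictly increasing within
#'   chromosomes.
#' @export
inject_snps <- function(genome, rate = 0.02, freq_model = c(0.05, 0.95),
                        seed = NULL) {
  stopifnot(inherits(genome, "radgs_genome"))
  assert_that(rate > 0 && rate < 1, "rate must lie in (0, 1)")
  assert_that(length(freq_model) == 2 && freq_model[1] > 0 && freq_model[2] < 1 &&
                freq_model[1] <= freq_model[2],
              "freq_model must be (min, max) within (0, 1)")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- lapply(names(genome$seq), function(ch) {
      L <- length(genome$seq[[ch]])
      k <- rbinom(1, L, rate)
      if (k == 0) {
        return(data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          freq = numeric(0)))
      }
      pos <- sort(sample.int(L, k)) - 1L
      ref <- as.character(Biostrings::extractAt(
        genome$seq[[ch]], IRanges::IRanges(pos + 1L, width = 1L)))
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      data.frame(chrom = ch, pos = pos, ref = unname(ref), alt = unname(alt),
                 freq = runif(k, freq_model[1], freq_model[2]))
    })
    cat_df <- do.call(rbind, out)
    rownames(cat_df) <- NULL
    class(cat_df) <- c("snp_catalogue", "data.frame")
    cat_df
  })
}
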