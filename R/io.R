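# Readers and writers for the standard interchange formats: genotypes
# (VCF / TSV), phenotypes (TSV), pedigrees (CSV), genomes (FASTA), SNP
# catalogues (sites-only VCF / TSV) and run configurations (YAML).
#
# Conventions: 0/1/2 genotype coding counts copies of the alternate allele
# (AA = 0, AB = 1, BB = 2 with B the alternate allele); BED is 0-based
# half-open; VCF positions are 1-based; the TSV genotype dialect has
# individuals in rows, a header of marker ids, an `id` first column, and
# "NA" for missing.

#' Read a genotype matrix
#'
#' Diploid GT fields are mapped to alternate-allele counts (0/1, 1/1, ./.
#' become 1, 2, NA); multi-allelic sites are skipped with a warning. The
#' TSV dialect is individuals x markers with an `id` column.
#'
#' @param path file path.
#' @param format "auto" (by extension), "vcf" or "tsv".
#' @return numeric matrix (individuals x markers) with NA for missing,
#'   marker ids as column names and individual ids as row names.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v))
    if (any(multi)) {
      warning(sum(multi), " multi-allelic site(s) skipped")
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a)
               sum(as.numeric(a)), numeric(1)))
    }
    X <- apply(gt, 2, count_alt)
    if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(rownames(gt), colnames(gt)))
    t(X)
  } else {
    df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
    assert_that(names(df)[1] == "id", "TSV genotypes must have an 'id' first column")
    X <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(X) <- "double"
    rownames(X) <- as.character(df$id)
    X
  }
}

#' Write a genotype matrix as VCF
#'
#' Minimal sites + GT VCF (v4.2). Genotypes must be integer 0/1/2 or NA
#' (round imputed values first).
#'
#' @param X genotype matrix (individuals x markers).
#' @param map data.frame with `chrom`, `pos` (0-based; written 1-based) and
#'   optionally `id`, `ref`, `alt` per marker.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(X, map, path) {
  stopifnot(ncol(X) == nrow(map))
  bad <- !(X %in% c(0, 1, 2) | is.na(X))
  assert_that(!any(bad), "genotypes must be 0/1/2 or NA for VCF export")
  gt <- matrix(c("0/0", "0/1", "1/1")[X + 1], nrow(X), ncol(X))
  gt[is.na(X)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=radgs",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(X) %||% paste0("ind", seq_len(nrow(X)))),
                    collapse = "\t"))
  body <- cbind(as.character(map$chrom), map$pos + 1L,
                if (!is.null(map$id)) as.character(map$id) else colnames(X) %||% paste0("m", seq_len(ncol(X))),
                if (!is.null(map$ref)) map$ref else "A",
                if (!is.null(map$alt)) map$alt else "T",
                ".", "PASS", ".", "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a genotype matrix as TSV
#' @param X genotype matrix (individuals x markers).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotypes_tsv <- function(X, path) {
  df <- data.frame(id = rownames(X) %||% paste0("ind", seq_len(nrow(X))),
                   X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a genome as FASTA
#' @param genome a `radgs_genome`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
genome_to_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "radgs_genome"))
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' Export a SNP catalogue
#'
#' @param snps a `snp_catalogue`.
#' @param path output path.
#' @param format "vcf" (sites-only, 1-based) or "tsv" (0-based positions).
#' @return the path, invisibly.
#' @export
catalogue_export <- function(snps, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2", "##source=radgs",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO"), collapse = "\t")), con)
    writeLines(paste(snps$chrom, snps$pos + 1L, ".", snps$ref, snps$alt,
                     ".", "PASS", sprintf("AF=%.4f", snps$freq), sep = "\t"), con)
  }
  invisible(path)
}

#' Write / read a pedigree as CSV
#'
#' Columns: id, sire, dam, family, generation.
#' @param ped pedigree data.frame (e.g. `pop$ped`).
#' @param path file path.
#' @return the path (write) or the pedigree data.frame (read).
#' @export
write_pedigree <- function(ped, path) {
  write.csv(ped[, intersect(c("id", "sire", "dam", "family", "generation"),
                            names(ped))], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  read.csv(path, na.strings = c("NA", ""), colClasses = "character")
}

#' Write / read a phenotype table as TSV
#' @param phen data.frame with an `id` column.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_phenotypes <- function(phen, path) {
  write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.delim(path, na.strings = c("NA", ""))
}

#' Export fitted marker effects
#'
#' Writes a tabular effects file (marker id, effect, posterior inclusion
#' probability where available) plus a JSON sidecar with variance
#' components, hyperparameters and diagnostics.
#'
#' @param fit a `gs_fit` with marker effects.
#' @param path output TSV path; the JSON metadata goes to `<path>.json`.
#' @return the path, invisibly.
#' @export
write_effects <- function(fit, path) {
  stopifnot(inherits(fit, "gs_fit"))
  assert_that(!is.null(fit$g), "fit has no per-marker effects")
  df <- data.frame(marker = names(fit$g) %||% seq_along(fit$g),
                   effect = unname(fit$g))
  if (!is.null(fit$pip)) df$pip <- fit$pip
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(method = fit$method,
               beta = as.list(fit$beta),
               varcomp = fit$varcomp[!vapply(fit$varcomp, is.null, logical(1))],
               diagnostics = fit$diagnostics[c("n_saved", "chain", "rhat_sigma_e2")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' @param path YAML file.
#' @return the configuration list, validated.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a run configuration
#'
#' Checks the schema used by [run_experiment()]: unknown keys are rejected
#' and defaults filled in.
#'
#' @param config configuration list.
#' @return validated configuration with defaults applied.
#' @export
validate_run_config <- function(config) {
  known <- c("design", "h2", "methods", "panels", "n_families",
             "replicates", "cv", "hyper", "scale", "seed",
             "dominance_share")
  extra <- setdiff(names(config), known)
  assert_that(length(extra) == 0,
              paste("unknown config key(s):", paste(extra, collapse = ", ")))
  assert_that(!is.null(config$design) &&
                config$design %in% c("sim1", "sim2", "sim3"),
              "config$design must be one of sim1, sim2, sim3")
  config$h2 <- config$h2 %||% 0.3
  assert_that(all(config$h2 > 0 & config$h2 <= 1), "h2 must lie in (0, 1]")
  config$methods <- config$methods %||% c("G-BLUP", "BayesA")
  config$panels <- config$panels %||% c("MD", "LD")
  config$replicates <- config$replicates %||% 1
  config$cv <- utils::modifyList(list(k = 5, repeats = 1), config$cv %||% list())
  config$hyper <- config$hyper %||% list()
  config$scale <- config$scale %||% list()
  config$seed <- config$seed %||% 1L
  config$dominance_share <- config$dominance_share %||% 0.3
  config
}
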