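# Marker panel construction: HD (even genomic spacing), MD (SNPs inside
# BsaXI tags) and LD (SNPs inside RTR tags).

#' Build high/medium/low density marker panels
#'
#' The HD panel contains `hd_size` catalogue SNPs chosen by even genomic
#' spacing. The MD panel contains every SNP whose position falls inside a
#' BsaXI tag interval, and the LD panel every SNP inside an RTR tag (so
#' LD is a subset of MD before any subsampling). Optional subsampling
#' reduces MD/LD to fixed sizes, mirroring the random 2b-RAD marker subsets
#' used for family-scale analyses.
#'
#' @param snps a `snp_catalogue`.
#' @param tags a `restriction_tags` data.frame (pre-RTR); tags with
#'   `is_rtr = TRUE` define the LD panel. Pass the output of
#'   [find_bsaxi_tags()] after marking RTR tags with [rtr_filter()], or pass
#'   the full tag set and supply `rtr_tags` separately.
#' @param hd_size number of HD loci (even spacing over the genome).
#' @param ld_subsample optional size to which the LD panel is randomly
#'   subsampled (e.g. 2364).
#' @param md_subsample optional size to which the MD panel is randomly
#'   subsampled, used to preserve a per-Mb density when the genome is scaled.
#' @param rtr_tags optional `restriction_tags` holding the RTR subset; if
#'   missing, rows of `tags` with `is_rtr = TRUE` are used.
#' @param exclude optional integer catalogue indices (e.g. QTL loci) removed
#'   from every panel.
#' @param seed optional integer seed for the subsampling.
#' @return named list of `marker_panel` objects (`HD`, `MD`, `LD`), each a
#'   list with `name`, `loci` (sorted unique catalogue row indices) and
#'   `density` (markers per Mb).
#' @export
build_marker_panels <- function(snps, tags, hd_size, ld_subsample = NULL,
                                md_subsample = NULL, rtr_tags = NULL,
                                exclude = NULL, seed = NULL) {
  stopifnot(inherits(snps, "snp_catalogue"))
  assert_that(nrow(snps) > 0, "SNP catalogue is empty")
  candidates <- setdiff(seq_len(nrow(snps)), exclude)
  assert_that(hd_size <= length(candidates),
              "hd_size exceeds the number of available catalogue loci")
  if (is.null(rtr_tags)) {
    rtr_tags <- tags[tags$is_rtr, , drop = FALSE]
  }

  chroms <- unique(snps$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch) {
    max(c(snps$pos[snps$chrom == ch], 0)) + 1
  }, numeric(1))))
  names(offsets) <- c(chroms, "end")
  glob <- snps$pos + offsets[snps$chrom]
  total <- offsets[length(offsets)]

  in_tags <- function(tagset) {
    if (is.null(tagset) || nrow(tagset) == 0) return(integer(0))
    hit <- logical(nrow(snps))
    for (ch in intersect(chroms, unique(tagset$chrom))) {
      sn <- which(snps$chrom == ch)
      tg <- tagset[tagset$chrom == ch, , drop = FALSE]
      ov <- IRanges::overlapsAny(
        IRanges::IRanges(snps$pos[sn] + 1L, width = 1L),
        IRanges::IRanges(tg$start + 1L, tg$end))
      hit[sn] <- ov
    }
    which(hit)
  }

  with_seed(seed, {
    # HD: nearest candidate SNP to each of hd_size evenly spaced targets
    cand_glob <- glob[candidates]
    ord <- order(cand_glob)
    cg <- cand_glob[ord]
    targets <- (seq_len(hd_size) - 0.5) / hd_size * total
    idx <- findInterval(targets, cg)
    pick <- vapply(seq_along(targets), function(i) {
      lo <- max(idx[i], 1L); hi <- min(idx[i] + 1L, length(cg))
      if (abs(cg[lo] - targets[i]) <= abs(cg[hi] - targets[i])) lo else hi
    }, integer(1))
    hd <- sort(unique(candidates[ord][pick]))

    md <- intersect(in_tags(tags), candidates)
    ld <- intersect(in_tags(rtr_tags), candidates)
    if (length(md) == 0) warning("MD panel is empty (no SNPs inside BsaXI tags)")
    if (length(ld) == 0) warning("LD panel is empty (no SNPs inside RTR tags)")
    # LD is a subset of MD as constructed; random subsampling below is
    # applied to each panel independently.
    if (!is.null(md_subsample) && md_subsample < length(md)) {
      md <- sort(sample(md, md_subsample))
    }
    if (!is.null(ld_subsample) && ld_subsample < length(ld)) {
      ld <- sort(sample(ld, ld_subsample))
    }
    mk <- function(name, loci) {
      structure(list(name = name, loci = sort(unique(loci)),
                     density = length(loci) / (total / 1e6)),
                class = "marker_panel")
    }
    list(HD = mk("HD", hd), MD = mk("MD", md), LD = mk("LD", ld))
  })
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel %s: %d loci (%.1f per Mb)\n",
              x$name, length(x$loci), x$density))
  invisible(x)
}

#' Write a marker panel as TSV
#'
#' @param panel a `marker_panel`.
#' @param snps the `snp_catalogue` the panel indexes into.
#' @param path output path.
#' @return the path, invisibly.
#' @export
panel_to_tsv <- function(panel, snps, path) {
  df <- data.frame(index = panel$loci,
                   chrom = snps$chrom[panel$loci],
                   pos = snps$pos[panel$loci])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
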