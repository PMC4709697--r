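# In silico type IIB (BsaXI) tag discovery and reduced tag representation.

BSAXI_PATTERN <- "NNNNNNNNNNACNNNNNCTCCNNNNNNNN"   # 29 bp, AC at 10, CTCC at 17
BSAXI_PATTERN_RC <- "NNNNNNNNGGAGNNNNNGTNNNNNNNNNN" # reverse complement motif

#' Locate BsaXI tags in a genome
#'
#' Scans for the 29-base BsaXI tag pattern N10-AC-N5-CTCC-N8. Matches are
#' reported in 0-based half-open coordinates; only full 29-mers entirely
#' inside a chromosome are returned, so sites too close to a chromosome end
#' to carry both flanks are dropped. With `search_both_strands = TRUE` the
#' reverse-complement motif (GGAG-N5-GT core) is also matched; a minus-strand
#' tag's sequence is reported on its own strand. Tags sharing the same
#' genomic interval on both strands are deduplicated (plus strand kept).
#'
#' @param genome a `radgs_genome`.
#' @param search_both_strands search the reverse strand as well (default
#'   TRUE); single-strand mode exists mainly for oracle testing.
#' @return a `restriction_tags` data.frame: `chrom`, `start`, `end` (0-based
#'   half-open, width 29), `strand`, `seq` (tag sequence on its strand),
#'   `is_rtr` (FALSE until [rtr_filter()] is applied).
#' @export
find_bsaxi_tags <- function(genome, search_both_strands = TRUE) {
  stopifnot(inherits(genome, "radgs_genome"))
  assert_that(length(genome$seq) > 0 && sum(Biostrings::width(genome$seq)) > 0,
              "genome is empty")
  scan_one <- function(pattern, strand) {
    hits <- Biostrings::vmatchPattern(pattern, genome$seq, fixed = FALSE)
    out <- lapply(seq_along(hits), function(i) {
      r <- hits[[i]]
      if (length(r) == 0) return(NULL)
      seqs <- as.character(Biostrings::extractAt(genome$seq[[i]], r))
      if (strand == "-") {
        seqs <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs)))
      }
      data.frame(chrom = names(genome$seq)[i],
                 start = IRanges::start(r) - 1L,
                 end = IRanges::end(r),
                 strand = strand, seq = seqs)
    })
    do.call(rbind, out)
  }
  tags <- scan_one(BSAXI_PATTERN, "+")
  if (search_both_strands) {
    tags <- rbind(tags, scan_one(BSAXI_PATTERN_RC, "-"))
  }
  if (is.null(tags)) {
    tags <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       seq = character(0))
  }
  tags <- tags[order(tags$chrom, tags$start, tags$strand), , drop = FALSE]
  dup <- duplicated(tags[, c("chrom", "start")])
  tags <- tags[!dup, , drop = FALSE]
  tags$is_rtr <- logical(nrow(tags))
  rownames(tags) <- NULL
  class(tags) <- c("restriction_tags", "data.frame")
  tags
}

#' Keep only reduced-tag-representation (RTR) BsaXI tags
#'
#' RTR libraries built with selective 5'-NNA-3' adaptor overhangs only ligate
#' tags of the form A-N9-AC-N5-CTCC-N7-T: the first base of the 29-mer must
#' be A and the last must be T on the tag's strand. Under uniform base
#' composition 1/16 of tags survive.
#'
#' @param tags a `restriction_tags` data.frame from [find_bsaxi_tags()].
#' @param genome optional `radgs_genome`; when given, tag coordinates are
#'   validated against it.
#' @return the retained tags with `is_rtr = TRUE`.
#' @export
rtr_filter <- function(tags, genome = NULL) {
  stopifnot(inherits(tags, "restriction_tags"))
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    assert_that(all(tags$chrom %in% names(lens)) &&
                  all(tags$end <= lens[tags$chrom]),
                "tags do not match the supplied genome")
  }
  keep <- substr(tags$seq, 1, 1) == "A" & substr(tags$seq, 29, 29) == "T"
  out <- tags[keep, , drop = FALSE]
  out$is_rtr <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("restriction_tags", "data.frame")
  out
}

#' Export restriction tags as BED
#'
#' Writes tags using the BED convention (0-based half-open) with name, score
#' and strand columns.
#'
#' @param tags a `restriction_tags` data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
tags_to_bed <- function(tags, path) {
  stopifnot(inherits(tags, "restriction_tags"))
  bed <- data.frame(tags$chrom, tags$start, tags$end,
                    name = paste0("tag", seq_len(nrow(tags))),
                    score = 0L, strand = tags$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
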