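# Marker quality control and mean imputation.

#' Filter markers on minor allele frequency and call rate
#'
#' Retains markers genotyped in at least `call_rate_min` of the individuals
#' with minor allele frequency strictly above `maf_min` (computed on the
#' observed genotypes).
#'
#' @param X genotype matrix with entries 0/1/2 or NA.
#' @param maf_min minor-allele-frequency threshold (exclusive), default 0.05.
#' @param call_rate_min call-rate threshold (inclusive), default 0.70.
#' @return list with `genotypes` (filtered matrix), `keep` (logical vector
#'   over the input markers) and `stats` (per-marker `maf` and `call_rate`).
#' @export
qc_filter <- function(X, maf_min = 0.05, call_rate_min = 0.70) {
  X <- as.matrix(X)
  call_rate <- colMeans(!is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  keep <- call_rate >= call_rate_min & !is.na(maf) & maf > maf_min
  if (!any(keep)) stop("all markers removed by QC", call. = FALSE)
  list(genotypes = X[, keep, drop = FALSE], keep = keep,
       stats = data.frame(marker = colnames(X) %||% seq_len(ncol(X)),
                          maf = maf, call_rate = call_rate,
                          row.names = NULL))
}

#' Mean imputation of missing genotypes
#'
#' Missing entries are replaced by the column mean of the observed genotypes
#' (the "mean algorithm"); observed entries are untouched, so each column
#' mean is conserved.
#'
#' @param X genotype matrix with NAs.
#' @param means optional vector of column means to impute with (use the
#'   training-set means when imputing a validation set).
#' @return numeric matrix without missing values.
#' @export
impute_mean <- function(X, means = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(means)) {
    means <- colMeans(X, na.rm = TRUE)
    if (anyNA(means) || any(is.nan(means)))
      stop("fully missing column; run qc_filter first", call. = FALSE)
  }
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- means[idx[, 2]]
  X
}
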