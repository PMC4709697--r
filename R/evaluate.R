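# Cross-validation and over-generation accuracy evaluation, plus the
# accuracy/bias metrics and multivariate diagnostics.

#' Cross-validation scheme
#'
#' @param k number of folds (default 5; 80% train / 20% validate).
#' @param repeats number of independent random k-fold partitions (the
#'   resampling count; each partition validates every individual once).
#' @param stratify "none" (default) or "family" for family-balanced folds.
#' @param seed optional integer seed.
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(k = 5, repeats = 100, stratify = c("none", "family"),
                      seed = NULL) {
  assert_that(k >= 2, "need at least 2 folds")
  structure(list(k = k, repeats = repeats,
                 stratify = match.arg(stratify), seed = seed),
            class = "cv_scheme")
}

make_folds <- function(n, k, families = NULL, stratify = "none") {
  if (stratify == "family" && !is.null(families)) {
    folds <- integer(n)
    for (f in unique(families)) {
      rows <- which(families == f)
      folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    folds
  } else {
    sample(rep_len(seq_len(k), n))
  }
}

fit_method <- function(method, data, hyper, A = NULL) {
  switch(method,
         "BLUP" = fit_pedigree_blup(data, A = A),
         "G-BLUP" = fit_gblup(data),
         "RR-BLUP" = fit_rrblup(data),
         "BayesA" = fit_bayesA(data, hyper),
         "BayesB" = fit_bayesB(data, hyper),
         "BL" = fit_bayesian_lasso(data, hyper),
         "LASSO" = fit_lasso(data, seed = hyper$seed),
         stop("unknown method: ", method))
}

#' Cross-validated prediction accuracy
#'
#' Repeated k-fold cross-validation of one or more genomic prediction
#' methods. Within each training split, markers are (optionally) QC-filtered
#' and missing genotypes mean-imputed using training-set means only;
#' variance components and penalties are likewise estimated inside the
#' split. Validation accuracy is the Pearson correlation of the predicted
#' breeding values with the true breeding values (`truth`, simulations) or
#' with the observed phenotypes (empirical mode, `truth = NULL`).
#'
#' @param y phenotype vector.
#' @param X genotype matrix (0/1/2; may contain NA when `qc = TRUE`).
#' @param methods character vector among BLUP, G-BLUP, RR-BLUP, BayesA,
#'   BayesB, BL, LASSO.
#' @param scheme a [cv_scheme()].
#' @param truth optional vector of true breeding values.
#' @param families optional family labels (used as fixed effects and for
#'   stratified folds).
#' @param A optional full relationship matrix over all samples (required for
#'   method "BLUP").
#' @param hyper a [gs_hyper()] for the Bayesian methods.
#' @param qc apply [qc_filter()] inside each training split.
#' @return an `accuracy_report` data.frame with one row per
#'   (repeat, fold, method): `accuracy`, `slope`, and `r_y` (correlation
#'   with the observed phenotype). Use [summary()] for means and SDs.
#' @export
cross_validate <- function(y, X, methods, scheme = cv_scheme(),
                           truth = NULL, families = NULL, A = NULL,
                           hyper = gs_hyper(), qc = FALSE) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  rows <- list()
  for (rep_i in seq_len(scheme$repeats)) {
    folds <- make_folds(n, scheme$k, families, scheme$stratify)
    for (f in seq_len(scheme$k)) {
      tr <- folds != f
      res <- eval_split(y, X, methods, tr, truth, families, A, hyper, qc)
      res$rep <- rep_i; res$fold <- f
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

# Fit all methods on rows `tr`, evaluate on the complement.
eval_split <- function(y, X, methods, tr, truth, families, A, hyper, qc) {
  Xtr <- X[tr, , drop = FALSE]
  Xva <- X[!tr, , drop = FALSE]
  if (qc || anyNA(Xtr)) {
    q <- qc_filter(Xtr)
    means <- colMeans(q$genotypes, na.rm = TRUE)
    Xtr <- impute_mean(q$genotypes)
    Xva <- impute_mean(Xva[, q$keep, drop = FALSE], means = means)
  }
  fam_tr <- if (is.null(families)) NULL else families[tr]
  fam_va <- if (is.null(families)) NULL else families[!tr]
  data <- gs_data(y[tr], Xtr, families = fam_tr)
  out <- lapply(methods, function(m) {
    fit <- fit_method(m, data, hyper,
                      A = if (m == "BLUP") A[tr, tr, drop = FALSE] else NULL)
    ebv <- if (m == "BLUP") {
      drop(A[!tr, tr, drop = FALSE] %*% fit$alpha) +
        family_effect(fit, fam_va)
    } else {
      predict_gebv(fit, X_new = Xva, families_new = fam_va)
    }
    ref <- if (is.null(truth)) y[!tr] else truth[!tr]
    acc <- safe_cor(ref, ebv)
    if (is.na(acc)) warning("constant EBV vector; accuracy undefined for one fold")
    data.frame(method = m, accuracy = acc,
               slope = if (sd(ebv) > 0) unname(coef(lm(y[!tr] ~ ebv))[2]) else NA_real_,
               r_y = safe_cor(y[!tr], ebv))
  })
  do.call(rbind, out)
}

#' @export
summary.accuracy_report <- function(object, ...) {
  sp <- split(object, object$method)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(method = d$method[1],
               n_eval = sum(!is.na(d$accuracy)),
               accuracy = mean(d$accuracy, na.rm = TRUE),
               accuracy_sd = sd(d$accuracy, na.rm = TRUE),
               slope = mean(d$slope, na.rm = TRUE),
               r_y = mean(d$r_y, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Over-generation prediction accuracy
#'
#' Trains each method on one generation and validates on the next: the
#' training phenotypes estimate the model, and the predicted breeding values
#' of the test individuals are correlated with their true breeding values.
#'
#' @param y_train,X_train training phenotypes and genotypes.
#' @param X_test genotypes of the next generation (same marker panel).
#' @param truth_test true breeding values of the test individuals (or their
#'   phenotypes in empirical mode).
#' @param methods methods to evaluate (as in [cross_validate()]).
#' @param families_train optional family labels for the training set.
#' @param A optional relationship matrix over (train, test) stacked rows for
#'   method "BLUP".
#' @param hyper a [gs_hyper()].
#' @return an `accuracy_report` with one row per method.
#' @export
over_generation_eval <- function(y_train, X_train, X_test, truth_test,
                                 methods, families_train = NULL, A = NULL,
                                 hyper = gs_hyper()) {
  assert_that(ncol(X_train) == ncol(X_test), "marker panels do not match")
  n_tr <- nrow(X_train)
  if (anyNA(X_train) || anyNA(X_test)) {
    q <- qc_filter(X_train)
    means <- colMeans(q$genotypes, na.rm = TRUE)
    X_train <- impute_mean(q$genotypes)
    X_test <- impute_mean(X_test[, q$keep, drop = FALSE], means = means)
  }
  data <- gs_data(y_train, X_train, families = families_train)
  rows <- lapply(methods, function(m) {
    fit <- fit_method(m, data, hyper,
                      A = if (m == "BLUP") A[seq_len(n_tr), seq_len(n_tr)] else NULL)
    ebv <- if (m == "BLUP") {
      drop(A[n_tr + seq_len(nrow(X_test)), seq_len(n_tr)] %*% fit$alpha)
    } else {
      predict_gebv(fit, X_new = X_test)
    }
    data.frame(method = m, accuracy = safe_cor(truth_test, ebv),
               slope = if (sd(ebv) > 0) unname(coef(lm(truth_test ~ ebv))[2]) else NA_real_,
               r_y = NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Heritability-adjusted prediction accuracy
#'
#' When true breeding values are unknown, the correlation between phenotype
#' and EBV underestimates the TBV accuracy by a factor of the square root of
#' heritability; the adjusted accuracy is `r / sqrt(h2)`.
#'
#' @param r_y_ebv correlation between observed phenotype and EBV.
#' @param h2 heritability of the trait (> 0).
#' @return adjusted accuracy; values above 1 are flagged with a warning.
#' @examples
#' adjusted_accuracy(0.36, 0.36) # 0.60
#' @export
adjusted_accuracy <- function(r_y_ebv, h2) {
  assert_that(all(h2 > 0), "h2 must be positive")
  out <- r_y_ebv / sqrt(h2)
  if (any(abs(out) > 1, na.rm = TRUE))
    warning("adjusted accuracy exceeds 1 in magnitude")
  out
}

#' Regression slope of phenotype on EBV (prediction bias)
#'
#' The ordinary least-squares slope of the observed phenotype on the
#' estimated breeding values; unbiased prediction gives a slope near 1.
#'
#' @param y_validation observed phenotypes.
#' @param ebv_validation predicted breeding values (non-constant).
#' @return the slope.
#' @export
bias_slope <- function(y_validation, ebv_validation) {
  assert_that(sd(ebv_validation) > 0, "EBV vector is constant; slope undefined")
  unname(coef(lm(y_validation ~ ebv_validation))[2])
}

#' Principal component analysis (centred SVD)
#'
#' Thin wrapper used for the genotype-structure and marker-effect
#' diagnostics: centred, unscaled PCA via singular value decomposition.
#'
#' @param x matrix (rows = observations).
#' @param n_components number of components to return.
#' @return list with `scores`, `explained_variance` (proportions,
#'   non-increasing) and `sdev`.
#' @export
pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  assert_that(!anyNA(x), "PCA requires a complete matrix")
  assert_that(nrow(x) > n_components, "fewer rows than components")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  ncmp <- min(n_components, ncol(pr$x))
  list(scores = pr$x[, seq_len(ncmp), drop = FALSE],
       explained_variance = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(ncmp)],
       sdev = pr$sdev)
}

#' Correlation of marker effects across fitted models
#'
#' Pearson correlations between the per-marker effect vectors of
#' marker-effect fits sharing a panel; the diagonal is 1 and pairs involving
#' a zero-variance effect vector are NA.
#'
#' @param fits named list of `gs_fit` objects with marker effects.
#' @return symmetric correlation matrix.
#' @export
marker_effect_correlation <- function(fits) {
  gs <- lapply(fits, function(f) {
    assert_that(!is.null(f$g), paste(f$method, "has no marker effects"))
    f$g
  })
  p <- unique(vapply(gs, length, integer(1)))
  assert_that(length(p) == 1, "fits do not share a marker panel")
  nm <- names(fits) %||% vapply(fits, function(f) f$method, character(1))
  G <- matrix(NA_real_, length(gs), length(gs), dimnames = list(nm, nm))
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    G[i, j] <- if (i == j) 1 else safe_cor(gs[[i]], gs[[j]])
  }
  G
}
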