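# L1-penalised regression of phenotypes on markers, solved by cyclic
# coordinate descent with soft-thresholding, warm starts along a decreasing
# penalty path, and the penalty chosen by internal cross-validation on the
# training records only. Fixed effects (intercept, family) are unpenalised
# and absorbed by projection.

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Coordinate descent for (1/(2n)) ||r - X g||^2 + lambda ||g||_1 on centred
# data; returns the whole path (warm-started). C++ inner loop.
lasso_path <- function(X, r, lambdas, tol = 1e-7, max_sweeps = 500) {
  lasso_path_cpp(X, r, lambdas, tol, as.integer(max_sweeps))
}

lasso_objective <- function(X, r, g, lam) {
  n <- nrow(X)
  sum((r - X %*% g)^2) / (2 * n) + lam * sum(abs(g))
}

#' LASSO regression of phenotypes on markers
#'
#' Solves the l1-penalised least-squares problem by coordinate descent. The
#' penalty is selected by `cv_folds`-fold cross-validation inside the
#' training data over a log-spaced path from `lambda_max` (the smallest
#' penalty that zeroes every effect) downwards.
#'
#' @param data a [gs_data] object.
#' @param lambda optional fixed penalty or vector path; a 50-point path is
#'   derived from the data when NULL.
#' @param cv_folds folds for the internal penalty selection (ignored when a
#'   single `lambda` is given).
#' @param seed optional integer seed for the internal fold assignment.
#' @return a `gs_fit` with sparse marker effects; `extra$lambda` records the
#'   selected penalty. A null model (all effects zero) is returned with a
#'   warning when the selected penalty removes everything.
#' @export
fit_lasso <- function(data, lambda = NULL, cv_folds = 5, seed = NULL) {
  stopifnot(inherits(data, "gs_data"))
  assert_that(sd(data$y) > 0, "y is constant")
  Xc <- centered_X(data)
  # absorb unpenalised fixed effects by projection
  qw <- qr(data$W)
  r <- qr.resid(qw, data$y)
  Xr <- qr.resid(qw, Xc)
  n <- length(r)
  lam_max <- max(abs(crossprod(Xr, r))) / n
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = 50))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  sel <- lambda[1]
  if (length(lambda) > 1) {
    folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    mse <- matrix(NA_real_, cv_folds, length(lambda))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      path <- lasso_path(Xr[tr, , drop = FALSE], r[tr], lambda)
      pred <- Xr[!tr, , drop = FALSE] %*% path
      mse[f, ] <- colMeans((r[!tr] - pred)^2)
    }
    sel <- lambda[which.min(colMeans(mse))]
  }
  g <- drop(lasso_path(Xr, r, lambda)[, match(sel, lambda)])
  if (all(g == 0)) warning("LASSO selected the null model (all effects zero)")
  beta <- qr.coef(qw, data$y - Xc %*% g)
  beta[is.na(beta)] <- 0
  new_gs_fit("LASSO", data, beta = setNames(beta, colnames(data$W)),
             g = setNames(g, colnames(data$X)),
             gebv = drop(Xc %*% g),
             varcomp = list(lambda = sel, n_nonzero = sum(g != 0)),
             extra = list(lambda = sel, lambda_path = lambda))
}
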