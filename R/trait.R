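# Trait architectures and heritability-controlled phenotypes.

#' Assign QTLs and allelic effects
#'
#' Randomly chooses `n_qtl` loci as QTLs and draws their additive allelic
#' effects from N(0, 1). When `dominance_ratio > 0`, raw dominance effects
#' are drawn N(0, 1) as well; they are rescaled to the target
#' dominance-variance share at phenotype time (see
#' [simulate_phenotypes()]), where the realized variances of the phenotyped
#' population are known.
#'
#' @param loci locus table (data.frame) or a single integer locus count.
#' @param n_qtl number of QTLs.
#' @param dominance_ratio target share of phenotypic variance due to
#'   dominance (0 disables dominance).
#' @param seed optional integer seed.
#' @return a `trait_architecture`: list with `qtl` (locus indices), `a`
#'   (additive effects), `d` (raw dominance effects, zero when disabled) and
#'   `dominance_ratio`.
#' @export
assign_qtl <- function(loci, n_qtl, dominance_ratio = 0, seed = NULL) {
  L <- if (is.data.frame(loci)) nrow(loci) else as.integer(loci)
  assert_that(n_qtl >= 1 && n_qtl <= L,
              "n_qtl must be between 1 and the locus count")
  assert_that(dominance_ratio >= 0 && dominance_ratio < 1,
              "dominance_ratio must lie in [0, 1)")
  with_seed(seed, {
    qtl <- sort(sample.int(L, n_qtl))
    a <- rnorm(n_qtl, 0, 1)
    d <- if (dominance_ratio > 0) rnorm(n_qtl, 0, 1) else numeric(n_qtl)
    structure(list(qtl = qtl, a = a, d = d,
                   dominance_ratio = dominance_ratio),
              class = "trait_architecture")
  })
}

#' True genetic values of a population
#'
#' The true (additive) breeding value of individual i is
#' `TBV_i = sum_j x_ij a_j` with x the 0/1/2 alternate-allele count at QTL j;
#' the dominance deviation adds `d_j` for each heterozygous QTL.
#'
#' @param pop a `gs_population`.
#' @param arch a `trait_architecture` whose QTL indices refer to `pop$loci`.
#' @return list with numeric vectors `tbv` and `dominance`.
#' @export
genetic_values <- function(pop, arch) {
  stopifnot(inherits(pop, "gs_population"),
            inherits(arch, "trait_architecture"))
  assert_that(max(arch$qtl) <= ncol(pop$H1),
              "architecture QTL indices exceed the population locus set")
  X <- pop$H1[, arch$qtl, drop = FALSE] + pop$H2[, arch$qtl, drop = FALSE]
  tbv <- drop(X %*% arch$a)
  dom <- if (any(arch$d != 0)) drop((X == 1L) %*% arch$d) else numeric(nrow(X))
  list(tbv = tbv, dominance = dom)
}

#' Simulate phenotypes at a target heritability
#'
#' Phenotypes are the genetic values plus a normally distributed error whose
#' variance is set from the realized additive variance of the supplied
#' individuals: `sigma_e^2 = sigma_A^2 (1 - h2) / h2` in the additive-only
#' case. With dominance, the variance shares of phenotype are additive
#' `h2`, dominance `dominance_share` and residual
#' `1 - h2 - dominance_share`; the dominance deviations are rescaled to hit
#' their share exactly (up to the sampling of the error term).
#'
#' @param tbv vector of true additive breeding values.
#' @param dominance vector of raw dominance deviations (or NULL).
#' @param h2 target narrow-sense heritability in (0, 1].
#' @param dominance_share target phenotypic variance share of dominance
#'   (default 0). Requires `h2 + dominance_share <= 1`.
#' @param seed optional integer seed.
#' @return a `phenotype_set`: data.frame with columns `tbv`,
#'   `dominance_dev`, `env`, `phenotype`, and attributes `realized_h2`,
#'   `var_components`.
#' @export
simulate_phenotypes <- function(tbv, dominance = NULL, h2,
                                dominance_share = 0, seed = NULL) {
  assert_that(h2 > 0 && h2 <= 1, "h2 must lie in (0, 1]")
  assert_that(dominance_share >= 0 && h2 + dominance_share <= 1,
              "h2 + dominance_share must not exceed 1")
  n <- length(tbv)
  var_a <- var(tbv)
  assert_that(is.finite(var_a) && var_a > 0,
              "realized additive variance is zero; cannot calibrate error")
  var_p <- var_a / h2
  dom <- rep(0, n)
  if (dominance_share > 0) {
    assert_that(!is.null(dominance) && var(dominance) > 0,
                "dominance_share > 0 requires non-degenerate dominance deviations")
    dom <- dominance * sqrt(dominance_share * var_p / var(dominance))
  }
  var_e <- var_p * (1 - h2 - dominance_share)
  with_seed(seed, {
    env <- if (var_e > 0) rnorm(n, 0, sqrt(var_e)) else rep(0, n)
    y <- tbv + dom + env
    out <- data.frame(tbv = tbv, dominance_dev = dom, env = env,
                      phenotype = y)
    attr(out, "var_components") <- c(var_a = var_a,
                                     var_d = if (dominance_share > 0) var(dom) else 0,
                                     var_e = var_e, var_p = var_p)
    attr(out, "realized_h2") <- var_a / var(y)
    class(out) <- c("phenotype_set", "data.frame")
    out
  })
}
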