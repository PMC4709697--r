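# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive reproducible stage seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent stage seeds
#' so that every stochastic stage of a pipeline can be seeded separately while
#' the whole run remains reproducible from a single integer.
#'
#' @param master single integer master seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Pearson correlation that returns NA (with a warning upstream) rather than
# erroring on degenerate input.
safe_cor <- function(a, b) {
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}
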