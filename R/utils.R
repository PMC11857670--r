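## Seed scoping and derivation. All stochastic code paths in the package go
## through these two helpers so a single master seed reproduces a run
## bit-for-bit without disturbing the caller's RNG state.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream of child seeds from a master seed
#'
#' Deterministic, collision-unlikely child seeds (kept below 2^31) for
#' replicates, per-algorithm fits, and per-species stages.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# round-half-up at `digits` decimals (report-time rounding convention;
# base round() is round-half-even)
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
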