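# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible child seeds from one parent seed. Children stay
# below 2^31 so they are valid R integer seeds.
childSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Format a numeric matrix/vector at 12 significant digits for TSV output;
# byte-stable across runs.
formatNum <- function(x) {
  formatC(x, digits = 12L, format = "g")
}

assertScalarNumeric <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}
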