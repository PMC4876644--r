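# Seed discipline: every stochastic generator evaluates under an explicit
# seed and restores the caller's RNG state afterwards, so generators are pure
# functions of their arguments.

.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("configuration error: seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a global seed
#'
#' Stable fan-out of one global seed into per-stage / per-item child seeds so
#' that pipeline stages are individually reproducible without seed
#' collisions. The derivation is a fixed polynomial hash reduced modulo
#' 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param ... one or more integer indices (stage, group, section, ...).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, 2, 3)
#' @export
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) * 16807 + 12345) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
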