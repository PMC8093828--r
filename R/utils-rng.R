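## Deterministic seed fan-out.
##
## A single master seed must drive every stochastic stage (simulation,
## rarefaction per sample, RF repeat runs, ordination, ellipse Monte Carlo)
## without the stages interfering with each other: adding a sample or a
## ladder level must not perturb the stream any earlier draw came from.
## Sub-seeds are derived by a small multiplicative-congruential hash over the
## index path, kept strictly below 2^31 so they are always valid R seeds.

.MOD31 <- 2147483647

#' Derive a deterministic sub-seed from a master seed and an index path
#'
#' @param seed master seed (single integer-valued number).
#' @param ... integer indices identifying the consumer (stage, level,
#'   sample, run, ...). Distinct paths give distinct, reproducible streams.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @keywords internal
.subSeed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) %% .MOD31) + 1
  for (k in idx) {
    s <- (s * 48271 + (as.double(k) + 11) * 7919) %% .MOD31
  }
  as.integer(s %% (.MOD31 - 2) + 1)
}

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so package functions never clobber the
## user's stream.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.assertCount <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < if (positive) 1 else 0) {
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(x))
}
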