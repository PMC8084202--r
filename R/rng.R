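# RNG substream plumbing.
#
# Every stochastic entry point takes a `seed`. Internally we use the
# L'Ecuyer-CMRG generator so that trial i of a simulation (or replicate b of a
# bootstrap) draws from its own independent substream: enlarging `numtrials`
# or `numboot` never perturbs the earlier trials/replicates, and an identical
# seed gives bit-identical output. The caller's RNG state is restored on exit.

# Returns a list of n L'Ecuyer-CMRG states, the first seeded from `seed`.
rng_substreams <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed), n >= 1)
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# Evaluate `expr` with .Random.seed set to `stream`; restores state after.
with_rng_stream <- function(stream, expr) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  assign(".Random.seed", stream, envir = globalenv())
  expr
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# A concrete integer seed: the one given, or one drawn from the current RNG
# so that seed = NULL still goes through the same substream machinery.
resolve_seed <- function(seed) {
  if (is.null(seed)) sample.int(.Machine$integer.max, 1) else as.integer(seed)
}

# n child seeds deterministically derived from a master seed (< 2^31).
derive_seeds <- function(seed, n) {
  with_rng_stream(rng_substreams(seed, 1)[[1]],
                  sample.int(.Machine$integer.max, n))
}
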