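# Isolated random-number streams.
#
# Every stochastic routine takes an integer seed and runs against its own
# RNG state, saved and restored around each draw, so package functions are
# reproducible without touching the caller's .Random.seed.

.seededRng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- .grabGlobalSeed()
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", envir = globalenv())
  .restoreGlobalSeed(old)
  e
}

.grabGlobalSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreGlobalSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.withRng <- function(rng, f) {
  old <- .grabGlobalSeed()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .restoreGlobalSeed(old)
  })
  f()
}

.rngSample <- function(rng, x, size) .withRng(rng, function() sample(x, size))

# a fresh sub-seed, e.g. for handing to compiled code (ranger)
.rngInt <- function(rng) .withRng(rng, function()
  sample.int(.Machine$integer.max - 1L, 1L))
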