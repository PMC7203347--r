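# Private seeded RNG streams.  Each stream owns a saved .Random.seed so
# module randomness is replayable and independent of the caller's RNG state.

make_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  e
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

sample_int <- function(rng, n, k, replace = FALSE, prob = NULL)
  with_rng(rng, sample.int(n, k, replace = replace, prob = prob))

rng_runif <- function(rng, n, min = 0, max = 1)
  with_rng(rng, stats::runif(n, min, max))

rng_rbinom <- function(rng, n, size, prob)
  with_rng(rng, stats::rbinom(n, size, prob))

rng_rnorm <- function(rng, n, mean = 0, sd = 1)
  with_rng(rng, stats::rnorm(n, mean, sd))
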