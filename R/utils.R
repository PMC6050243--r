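# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness (permutations, scrambles, simulators) flows through
# this helper so results are reproducible per seed and calls do not disturb
# the global stream.
withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
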