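# Run code with a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that a
# single integer seed makes them bit-reproducible without clobbering the
# session generator.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for a named pipeline stage, so stages can be
# re-run individually yet reproduce the full-run stream.
child_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

# sample() without its length-1 surprise
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
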