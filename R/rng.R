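# Deterministic per-replica RNG streams. Each stream is an independent
# L'Ecuyer-CMRG substream derived from the master seed, so adding or
# reordering replicas cannot change another replica's draws.

make_rng_streams <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- rng_stream(s)
    s <- parallel::nextRNGStream(s)
  }
  streams
}

rng_stream <- function(state) {
  e <- new.env(parent = emptyenv())
  e$state <- state
  class(e) <- "rng_stream"
  e
}

# Evaluate a sampling expression under a stream's state.
with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

rng_runif <- function(stream, n = 1L) with_stream(stream, stats::runif(n))
rng_rnorm <- function(stream, n = 1L, sd = 1) with_stream(stream, stats::rnorm(n, sd = sd))
rng_sample <- function(stream, x, size) with_stream(stream, sample(x, size))
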