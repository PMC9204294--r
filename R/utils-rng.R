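# Seeded sub-stream machinery.  All stochastic pieces of a fit (weight
# init, epoch shuffling/oversampling draws, the reparameterization noise
# epsilon) draw from separate saved RNG states derived from one master
# seed, so e.g. changing the number of epsilon draws never perturbs the
# data shuffle.  States are swapped in and out of .Random.seed.

# Deterministic integer hash of up to three small integers into [1, 2^31-2].
# Multipliers are small enough that the products stay exact in doubles.
.sub_seed <- function(master, a = 0L, b = 0L) {
  h <- (abs(as.numeric(master)) * 1103 + as.numeric(a) * 12289 +
          as.numeric(b) * 331 + 17) %% 2147483646
  as.integer(h) + 1L
}

.rng_stream <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  st
}

# Evaluate expr with the stream's RNG state active; save the advanced
# state back into the stream and restore the caller's state.
.with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
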