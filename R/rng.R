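# Named RNG streams.
#
# The optimizer draws randomness from separate named streams (init / ant /
# levy / cl / folds), each seeded deterministically from the master seed.
# Disabling one phase therefore leaves every other phase's draws untouched,
# which is what makes the ablation comparison paired rather than merely
# repeated. Streams are implemented by swapping .Random.seed in and out of
# the global environment around each draw.

save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# sub-seed derivation must stay inside 32-bit integer range
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  (as.numeric(seed) * 48271 + h) %% 2147483647
}

make_streams <- function(seed, names) {
  streams <- new.env(parent = emptyenv())
  old <- save_rng()
  for (nm in names) {
    set.seed(derive_seed(seed, nm))
    assign(nm, get(".Random.seed", envir = globalenv()), envir = streams)
  }
  restore_rng(old)
  streams
}

# evaluate expr with the named stream active, then park its advanced state
with_stream <- function(streams, name, expr) {
  old <- save_rng()
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    restore_rng(old)
  })
  expr
}
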