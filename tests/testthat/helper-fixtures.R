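# Small in-code fixtures shared across test files.

# a tiny, fully separable two-class dataset
tiny_dataset <- function(n = 12L, m = 6L, seed = 42L) {
  sim <- synthetic_expression(n_samples = n, n_genes = m, n_informative = 2L,
                              effect_size = 6, seed = seed)
  sim$dataset
}

# deterministic surrogate objective with a planted optimum: rewards matching
# the target mask bit-for-bit, with a small parsimony pull. The unique global
# optimum over all masks is the target itself.
surrogate_fitness <- function(target) {
  n <- length(target)
  function(mask) {
    1 - sum(abs(mask - target)) / n - 0.01 * sum(mask) / n
  }
}

repair_mask_for_test <- function(mask) {
  mask <- as.integer(mask)
  if (sum(mask) == 0L) mask[1L] <- 1L
  mask
}

# exhaustive enumeration oracle over all non-empty masks of length n
enumerate_best <- function(fitness_fn, n) {
  best_fit <- -Inf
  best_mask <- NULL
  for (code in seq_len(2^n - 1L)) {
    mask <- as.integer(intToBits(code)[seq_len(n)])
    f <- fitness_fn(mask)
    if (f > best_fit) {
      best_fit <- f
      best_mask <- mask
    }
  }
  list(mask = best_mask, fitness = best_fit)
}
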