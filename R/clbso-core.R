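#' Control parameters for the swarm optimizer
#'
#' Collects every knob of the hybrid swarm. Defaults follow the reference
#' configuration for expression data: a population of 50 binary masks
#' evolved for 100 iterations, initial inclusion probability 0.5, pheromone
#' decay 0.1, Levy step size 0.1 and binarization threshold 0.5.
#'
#' @param n_pop population size N (>= 2).
#' @param max_iter number of iterations T_max (>= 1).
#' @param p_init initial per-gene inclusion probability, in (0, 1).
#' @param rho pheromone decay rate, in (0, 1).
#' @param alpha,beta exponents weighting pheromone concentration against its
#'   complement in the toggle distribution.
#' @param s Levy flight step size (> 0).
#' @param sigma Levy scale factor (> 0).
#' @param threshold binarization threshold T mapping continuous positions
#'   back to bits, in (0, 1).
#' @param weights `c(w1, w2)`: accuracy weight and subset-size penalty
#'   weight of the objective.
#' @param n_toggles genes toggled per ant per iteration.
#' @param tau_min,tau_max clamp bounds of the pheromone vector; keeping both
#'   strictly inside (0, 1) guarantees a nonzero toggle distribution.
#' @param comprehensive_learning run the adaptive comprehensive-learning
#'   phase? Setting `FALSE` ablates that phase and leaves every other
#'   phase's random draws unchanged.
#' @return A list of class `clbso_control`.
#' @export
clbso_control <- function(n_pop = 50L, max_iter = 100L, p_init = 0.5,
                          rho = 0.1, alpha = 1, beta = 1, s = 0.1, sigma = 1,
                          threshold = 0.5, weights = c(0.99, 0.01),
                          n_toggles = 1L, tau_min = 0.01, tau_max = 0.99,
                          comprehensive_learning = TRUE) {
  stopifnot(n_pop >= 2L, max_iter >= 1L,
            p_init > 0, p_init < 1, rho > 0, rho < 1,
            s > 0, sigma > 0, threshold > 0, threshold < 1,
            n_toggles >= 1L,
            tau_min > 0, tau_max < 1, tau_min < tau_max,
            length(weights) == 2L, weights[1L] > 0, weights[2L] >= 0,
            is.logical(comprehensive_learning))
  structure(list(n_pop = as.integer(n_pop), max_iter = as.integer(max_iter),
                 p_init = p_init, rho = rho, alpha = alpha, beta = beta,
                 s = s, sigma = sigma, threshold = threshold,
                 weights = weights, n_toggles = as.integer(n_toggles),
                 tau_min = tau_min, tau_max = tau_max,
                 comprehensive_learning = comprehensive_learning),
            class = "clbso_control")
}

#' Initialize a population of binary feature masks
#'
#' Each bit is set independently with probability `p_init`; any all-zero
#' mask is repaired by switching on one uniformly chosen gene, so every
#' member starts with a non-empty subset.
#'
#' @param n_genes mask length.
#' @param n_pop number of masks.
#' @param p_init inclusion probability.
#' @return Integer matrix, `n_pop` rows x `n_genes` columns, entries 0/1.
#' @export
initialize_population <- function(n_genes, n_pop, p_init) {
  pop <- matrix(as.integer(stats::runif(n_pop * n_genes) < p_init),
                n_pop, n_genes)
  for (i in seq_len(n_pop)) pop[i, ] <- repair_mask(pop[i, ])
  pop
}

# all-zero masks are invalid: switch on one uniformly chosen gene
repair_mask <- function(mask) {
  if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
  mask
}

#' Pheromone vector update
#'
#' Decays every gene's pheromone by `1 - rho` and adds a deposit
#' proportional to how often the gene appears in good solutions:
#' `delta_j = mean_i( X_ij * max(f_i, 0) / F_max )` when the current best
#' fitness `F_max` is positive, and 0 otherwise. The result is clamped to
#' `[tau_min, tau_max]`.
#'
#' @param tau current pheromone vector.
#' @param population 0/1 mask matrix (individuals in rows).
#' @param fitnesses fitness per individual.
#' @param f_max current best fitness in the population.
#' @param rho decay rate in (0, 1).
#' @param tau_min,tau_max clamp bounds.
#' @return Updated pheromone vector.
#' @export
update_pheromone <- function(tau, population, fitnesses, f_max, rho,
                             tau_min = 0.01, tau_max = 0.99) {
  stopifnot(nrow(population) == length(fitnesses),
            ncol(population) == length(tau))
  if (f_max > 0) {
    quality <- pmax(fitnesses, 0) / f_max
    delta <- as.numeric(crossprod(population, quality)) / nrow(population)
  } else {
    delta <- 0
  }
  pmin(pmax((1 - rho) * tau + delta, tau_min), tau_max)
}

#' Toggle distribution over genes
#'
#' The categorical distribution the ants draw from:
#' `p_j = tau_j^alpha * (1 - tau_j)^beta / sum_k tau_k^alpha (1 - tau_k)^beta`.
#' With `alpha = beta = 1` it peaks for undecided genes (tau near 0.5) and
#' shrinks for genes the swarm has settled on (tau near either clamp), so
#' exploration focuses where the evidence is still ambiguous.
#'
#' @param tau pheromone vector, entries strictly inside (0, 1).
#' @param alpha,beta exponents.
#' @return Probability vector over genes summing to 1.
#' @export
toggle_probabilities <- function(tau, alpha = 1, beta = 1) {
  w <- tau^alpha * (1 - tau)^beta
  total <- sum(w)
  stopifnot(is.finite(total), total > 0)
  w / total
}

#' Ant local-search step for one individual
#'
#' Draws `n_toggles` distinct genes from the toggle distribution, flips them
#' to form a candidate mask (repaired if empty), and accepts the candidate
#' only if its fitness is strictly better than the incumbent's.
#'
#' @param mask incumbent 0/1 mask.
#' @param fit incumbent fitness (so it need not be recomputed).
#' @param probs toggle distribution from [toggle_probabilities()].
#' @param n_toggles number of distinct genes to flip.
#' @param fitness_fn objective function over masks.
#' @return List with `mask`, `fitness` (the survivor and its fitness),
#'   `proposal` (the candidate's bits, accepted or not) and `accepted`.
#' @export
ant_local_search <- function(mask, fit, probs, n_toggles, fitness_fn) {
  flip <- sample.int(length(mask), size = min(n_toggles, length(mask)),
                     prob = probs)
  cand <- mask
  cand[flip] <- 1L - cand[flip]
  cand <- repair_mask(cand)
  f_cand <- fitness_fn(cand)
  if (f_cand > fit) list(mask = cand, fitness = f_cand, proposal = cand,
                         accepted = TRUE)
  else list(mask = mask, fitness = fit, proposal = cand, accepted = FALSE)
}

#' Sample a Levy-flight step vector
#'
#' Heavy-tailed steps via the Mantegna scheme with stability index 1.5:
#' `step_j = s * sigma * u_j / |v_j|^(1/1.5)` with `u_j ~ N(0, sigma_u^2)`,
#' `v_j ~ N(0, 1)` and `sigma_u` the Mantegna constant. Steps are symmetric
#' about zero (the sign comes from `u`), mostly small, with occasional jumps
#' many times the median — the long leaps that let the grasshopper phase
#' escape local optima.
#'
#' @param n_genes number of components.
#' @param s step size; steps scale exactly linearly in `s`.
#' @param sigma scale factor.
#' @return Numeric step vector of length `n_genes`.
#' @export
levy_step <- function(n_genes, s = 0.1, sigma = 1) {
  stopifnot(s > 0, sigma > 0)
  lambda <- 1.5
  sigma_u <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
                (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
  u <- stats::rnorm(n_genes, sd = sigma_u)
  v <- stats::rnorm(n_genes)
  s * sigma * u / abs(v)^(1 / lambda)
}

#' Grasshopper global-search step for one individual
#'
#' Adds the Levy step to the 0/1 mask, binarizes the continuous result at
#' `threshold` (bit set iff the component exceeds it), repairs an empty
#' candidate, and applies the same strict greedy acceptance as the ant
#' phase. A zero step leaves the mask unchanged.
#'
#' @param mask incumbent 0/1 mask.
#' @param fit incumbent fitness.
#' @param step numeric step vector of the same length.
#' @param threshold binarization threshold T.
#' @param fitness_fn objective function over masks.
#' @return List with `mask`, `fitness`, `proposal`, `accepted`; see
#'   [ant_local_search()].
#' @export
grasshopper_move <- function(mask, fit, step, threshold, fitness_fn) {
  stopifnot(length(step) == length(mask))
  cand <- as.integer((mask + step) > threshold)
  cand <- repair_mask(cand)
  if (all(cand == mask))
    return(list(mask = mask, fitness = fit, proposal = cand, accepted = FALSE))
  f_cand <- fitness_fn(cand)
  if (f_cand > fit) list(mask = cand, fitness = f_cand, proposal = cand,
                         accepted = TRUE)
  else list(mask = mask, fitness = fit, proposal = cand, accepted = FALSE)
}

#' Per-gene success scores of the two search behaviours
#'
#' For each gene j, sums fitness-weighted membership over the population:
#' `S_A_j = sum_i (f_A_i / F_max) X_ij`, and likewise `S_G_j` with the
#' post-grasshopper fitnesses. `X_ij` are the current (post-grasshopper)
#' masks. When `F_max <= 0` the ratios are meaningless and all scores are 0.
#'
#' @param f_a,f_g per-individual fitnesses attributed to the ant and
#'   grasshopper phases.
#' @param f_max best fitness in the current population.
#' @param population current 0/1 mask matrix.
#' @return List with numeric vectors `s_a` and `s_g` over genes.
#' @export
success_scores <- function(f_a, f_g, f_max, population) {
  stopifnot(length(f_a) == nrow(population), length(f_g) == nrow(population))
  if (f_max <= 0) {
    zero <- numeric(ncol(population))
    return(list(s_a = zero, s_g = zero))
  }
  list(s_a = as.numeric(crossprod(population, f_a / f_max)),
       s_g = as.numeric(crossprod(population, f_g / f_max)))
}

#' Adaptive phase weights
#'
#' Normalizes the summed success scores of the two behaviours:
#' `W_A = sum(S_A) / (sum(S_A) + sum(S_G))` and `W_G = 1 - W_A`. When both
#' sums are zero (no attributable success yet) the weights fall back to
#' (0.5, 0.5).
#'
#' @param s_a,s_g success-score vectors from [success_scores()].
#' @return Named numeric `c(w_a = ..., w_g = ...)` summing to 1.
#' @export
adaptive_weights <- function(s_a, s_g) {
  stopifnot(length(s_a) == length(s_g))
  total <- sum(s_a) + sum(s_g)
  if (total == 0) return(c(w_a = 0.5, w_g = 0.5))
  c(w_a = sum(s_a) / total, w_g = sum(s_g) / total)
}

#' Comprehensive-learning update for one individual
#'
#' Blends the individual's ant and grasshopper proposals, encoded as signed
#' moves relative to the incumbent (`A_j = ant_bit_j - X_j`, in
#' \{-1, 0, +1\}), into a continuous position
#' `x_j = X_j + W_A * A_j + W_G * G_j`, binarizes it at `threshold`, repairs
#' an empty result, and applies strict greedy acceptance. With `W_A = 1` the
#' update reproduces the ant proposal exactly; likewise for `W_G = 1`.
#'
#' @param mask incumbent 0/1 mask.
#' @param fit incumbent fitness.
#' @param proposal_a,proposal_g the 0/1 candidate masks recorded by the ant
#'   and grasshopper phases this iteration.
#' @param w_a,w_g adaptive weights.
#' @param threshold binarization threshold.
#' @param fitness_fn objective function over masks.
#' @return List with `mask`, `fitness`, `accepted`.
#' @export
comprehensive_update <- function(mask, fit, proposal_a, proposal_g,
                                 w_a, w_g, threshold, fitness_fn) {
  x <- mask + w_a * (proposal_a - mask) + w_g * (proposal_g - mask)
  cand <- as.integer(x > threshold)
  cand <- repair_mask(cand)
  if (all(cand == mask))
    return(list(mask = mask, fitness = fit, accepted = FALSE))
  f_cand <- fitness_fn(cand)
  if (f_cand > fit) list(mask = cand, fitness = f_cand, accepted = TRUE)
  else list(mask = mask, fitness = fit, accepted = FALSE)
}

# best-so-far ordering: higher fitness, then fewer genes, then
# lexicographically smallest mask — deterministic and parsimony-aligned
better_than <- function(fit, mask, best_fit, best_mask, tol = 0) {
  if (fit > best_fit + tol) return(TRUE)
  if (fit < best_fit - tol) return(FALSE)
  if (sum(mask) < sum(best_mask)) return(TRUE)
  if (sum(mask) > sum(best_mask)) return(FALSE)
  d <- which(mask != best_mask)
  length(d) > 0L && mask[d[1L]] < best_mask[d[1L]]
}

#' Run the hybrid swarm optimizer over binary masks
#'
#' The engine behind [clbso()]: maximizes an arbitrary objective over 0/1
#' masks of length `n_genes`. Each iteration runs, for every individual, the
#' pheromone update, the ant local-search step, the grasshopper Levy-flight
#' step and (unless ablated) the comprehensive-learning blend, with strict
#' greedy acceptance throughout, so the best-so-far fitness never decreases.
#' Randomness is drawn from named per-phase streams derived from `seed`, so
#' runs are exactly reproducible and disabling the comprehensive-learning
#' phase does not perturb the other phases' draws.
#'
#' @param fitness_fn objective function mapping a 0/1 mask to a scalar;
#'   typically from [make_fitness()], but any deterministic function works
#'   (e.g. a surrogate objective in tests).
#' @param n_genes mask length.
#' @param control a [clbso_control()] list.
#' @param seed integer master seed.
#' @return A list of class `clbso_fit`: `best_mask`, `best_fitness`,
#'   `trace` (data.frame with one row per iteration: `iteration`,
#'   `best_fitness`, `n_selected`, `w_a`, `w_g`), final `population`,
#'   `fitnesses`, `pheromone`, plus `control` and `seed`.
#' @export
clbso_optimize <- function(fitness_fn, n_genes, control = clbso_control(),
                           seed = 1L) {
  stopifnot(inherits(control, "clbso_control"), n_genes >= 1L)
  streams <- make_streams(seed, c("init", "ant", "levy", "cl"))
  n_pop <- control$n_pop

  pop <- with_stream(streams, "init",
                     initialize_population(n_genes, n_pop, control$p_init))
  fits <- apply(pop, 1L, fitness_fn)
  tau <- rep(0.5, n_genes)

  best_i <- which.max(fits)
  best_mask <- pop[best_i, ]
  best_fit <- fits[best_i]
  for (i in seq_len(n_pop)) # settle initial ties by the deterministic order
    if (better_than(fits[i], pop[i, ], best_fit, best_mask)) {
      best_fit <- fits[i]; best_mask <- pop[i, ]
    }

  trace <- data.frame(iteration = seq_len(control$max_iter),
                      best_fitness = NA_real_, n_selected = NA_integer_,
                      w_a = NA_real_, w_g = NA_real_)

  for (t in seq_len(control$max_iter)) {
    prev_best <- best_fit

    tau <- update_pheromone(tau, pop, fits, max(fits), control$rho,
                            control$tau_min, control$tau_max)
    stopifnot(all(tau >= control$tau_min), all(tau <= control$tau_max))
    probs <- toggle_probabilities(tau, control$alpha, control$beta)
    stopifnot(abs(sum(probs) - 1) < 1e-12)

    prop_a <- matrix(0L, n_pop, n_genes)
    f_a <- numeric(n_pop)
    with_stream(streams, "ant", {
      for (i in seq_len(n_pop)) {
        res <- ant_local_search(pop[i, ], fits[i], probs,
                                control$n_toggles, fitness_fn)
        pop[i, ] <- res$mask; fits[i] <- res$fitness
        prop_a[i, ] <- res$proposal; f_a[i] <- res$fitness
      }
    })

    prop_g <- matrix(0L, n_pop, n_genes)
    f_g <- numeric(n_pop)
    with_stream(streams, "levy", {
      for (i in seq_len(n_pop)) {
        step <- levy_step(n_genes, control$s, control$sigma)
        res <- grasshopper_move(pop[i, ], fits[i], step,
                                control$threshold, fitness_fn)
        pop[i, ] <- res$mask; fits[i] <- res$fitness
        prop_g[i, ] <- res$proposal; f_g[i] <- res$fitness
      }
    })

    w <- c(w_a = NA_real_, w_g = NA_real_)
    if (control$comprehensive_learning) {
      scores <- success_scores(f_a, f_g, max(fits), pop)
      w <- adaptive_weights(scores$s_a, scores$s_g)
      stopifnot(abs(sum(w) - 1) < 1e-12)
      with_stream(streams, "cl", {
        for (i in seq_len(n_pop)) {
          res <- comprehensive_update(pop[i, ], fits[i],
                                      prop_a[i, ], prop_g[i, ],
                                      w[["w_a"]], w[["w_g"]],
                                      control$threshold, fitness_fn)
          pop[i, ] <- res$mask; fits[i] <- res$fitness
        }
      })
    }

    stopifnot(all(pop %in% c(0L, 1L)), all(rowSums(pop) >= 1L))
    for (i in seq_len(n_pop))
      if (better_than(fits[i], pop[i, ], best_fit, best_mask)) {
        best_fit <- fits[i]; best_mask <- pop[i, ]
      }
    stopifnot(best_fit >= prev_best)

    trace$best_fitness[t] <- best_fit
    trace$n_selected[t] <- sum(best_mask)
    trace$w_a[t] <- w[["w_a"]]
    trace$w_g[t] <- w[["w_g"]]
  }

  structure(list(best_mask = best_mask, best_fitness = best_fit,
                 trace = trace, population = pop, fitnesses = fits,
                 pheromone = tau, control = control, seed = seed),
            class = "clbso_fit")
}
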