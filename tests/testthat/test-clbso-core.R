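test_that("population initialization honours p and repairs empty masks", {
  set.seed(1)
  expect_true(all(initialize_population(20, 10, p_init = 1 - 1e-12) == 1L))

  pop0 <- initialize_population(20, 10, p_init = 1e-12)
  expect_true(all(rowSums(pop0) == 1L)) # all-zero masks repaired to one bit

  # ones-counts concentrate around n * p (3 binomial SDs)
  pop <- initialize_population(1000, 50, p_init = 0.5)
  expect_true(all(abs(rowSums(pop) - 500) <= 3 * sqrt(1000 * 0.25)))
})

test_that("pheromone update matches direct arithmetic and clamps", {
  # tau' = (1 - rho) * tau + delta; single individual containing gene 1 only,
  # fitness equal to the maximum, so delta = (1, 0)
  pop <- matrix(c(1L, 0L), 1, 2)
  tau <- update_pheromone(c(0.5, 0.5), pop, fitnesses = 1, f_max = 1,
                          rho = 0.1)
  # gene 1: 0.45 + 1 clamped at 0.99; gene 2 decays: 0.45
  expect_equal(tau, c(0.99, 0.45))

  # genes in no mask only decay
  tau2 <- update_pheromone(c(0.5, 0.08), matrix(0L, 2, 2), c(0.2, 0.1),
                           f_max = 0.2, rho = 0.1)
  expect_equal(tau2, c(0.45, 0.9 * 0.08))

  # non-positive best fitness: deposits switch off, decay still applies
  tau3 <- update_pheromone(c(0.5, 0.5), pop, fitnesses = -0.2, f_max = -0.2,
                           rho = 0.1)
  expect_equal(tau3, c(0.45, 0.45))
})

test_that("toggle probabilities normalize and match hand arithmetic", {
  expect_equal(toggle_probabilities(rep(0.3, 5)), rep(0.2, 5))
  expect_equal(toggle_probabilities(c(0.9, 0.2, 0.7), alpha = 0, beta = 0),
               rep(1 / 3, 3))
  # tau = (0.9, 0.5): weights (0.09, 0.25)
  p <- toggle_probabilities(c(0.9, 0.5))
  expect_equal(p, c(0.09, 0.25) / 0.34)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("ant local search is greedy and never decreases fitness", {
  popcount <- function(mask) sum(mask)
  set.seed(11)
  # flipping any 0 bit strictly increases popcount, so it is always accepted
  mask <- c(0L, 0L, 1L, 0L)
  res <- ant_local_search(mask, popcount(mask), rep(0.25, 4), 1, popcount)
  if (res$accepted) expect_gt(sum(res$mask), sum(mask))
  expect_gte(res$fitness, popcount(mask))

  # with a constant fitness no candidate is strictly better
  const <- function(mask) 0.5
  res2 <- ant_local_search(mask, 0.5, rep(0.25, 4), 2, const)
  expect_false(res2$accepted)
  expect_identical(res2$mask, mask)
  expect_false(all(res2$proposal == mask)) # the proposal is still recorded

  # repeated stochastic calls never violate the greedy guarantee
  for (i in 1:20) {
    m <- repair_mask_for_test(rbinom(6, 1, 0.5))
    r <- ant_local_search(m, popcount(m), rep(1 / 6, 6), 1, popcount)
    expect_gte(r$fitness, popcount(m))
  }
})

test_that("levy steps are deterministic, linear in s, and heavy-tailed", {
  set.seed(5); a <- levy_step(100, s = 0.1)
  set.seed(5); b <- levy_step(100, s = 0.1)
  expect_identical(a, b)

  set.seed(5); d <- levy_step(100, s = 0.2)
  expect_equal(d, 2 * a)

  set.seed(6)
  draws <- abs(levy_step(1e5, s = 0.1))
  expect_gt(quantile(draws, 0.999), 20 * median(draws))
  # steps are signed both ways
  set.seed(6)
  signs <- sign(levy_step(1e4, s = 0.1))
  expect_gt(mean(signs > 0), 0.4)
  expect_gt(mean(signs < 0), 0.4)
})

test_that("grasshopper binarization thresholds components at T", {
  popcount <- function(mask) sum(mask)
  mask <- c(1L, 0L, 0L, 1L)
  # zero step keeps the mask: 1 > 0.5, 0 is not
  res <- grasshopper_move(mask, popcount(mask), rep(0, 4), 0.5, popcount)
  expect_identical(res$mask, mask)
  expect_false(res$accepted)

  # component 0.7 -> bit 1, component 0.3 -> bit 0
  res2 <- grasshopper_move(c(0L, 0L, 0L, 0L), 0, c(0.7, 0.3, 0.6, 0.1),
                           0.5, popcount)
  expect_identical(res2$proposal, c(1L, 0L, 1L, 0L))
  expect_true(res2$accepted) # popcount strictly increased

  # a worse candidate is rejected and fitness kept
  negcount <- function(mask) -sum(mask)
  res3 <- grasshopper_move(c(1L, 0L), negcount(c(1L, 0L)), c(0, 0.9), 0.5,
                           negcount)
  expect_identical(res3$mask, c(1L, 0L))
  expect_equal(res3$fitness, -1)
})

test_that("success scores and adaptive weights match hand arithmetic", {
  # one individual at the maximum: scores reproduce its mask
  s <- success_scores(f_a = 1, f_g = 1, f_max = 1,
                      population = matrix(c(1L, 0L, 1L), 1))
  expect_equal(s$s_a, c(1, 0, 1))

  # two individuals, fitness ratios 1.0 and 0.5, masks (1,0) and (1,1)
  pop <- rbind(c(1L, 0L), c(1L, 1L))
  s2 <- success_scores(f_a = c(1, 0.5), f_g = c(1, 0.5), f_max = 1, pop)
  expect_equal(s2$s_a, c(1.5, 0.5))

  # genes in no mask score zero
  expect_equal(success_scores(c(1, 1), c(1, 1), 1, matrix(0L, 2, 3))$s_a,
               c(0, 0, 0))

  # degenerate best fitness: all scores zero, weights fall back to 1/2
  s3 <- success_scores(c(0.5, 0.2), c(0.3, 0.2), f_max = -0.1, pop)
  expect_equal(s3$s_a, c(0, 0))
  expect_equal(adaptive_weights(s3$s_a, s3$s_g), c(w_a = 0.5, w_g = 0.5))

  expect_equal(adaptive_weights(c(2, 1), c(2, 1)), c(w_a = 0.5, w_g = 0.5))
  expect_equal(adaptive_weights(c(0, 0), c(1, 2)), c(w_a = 0, w_g = 1))
  expect_equal(adaptive_weights(c(3, 0), c(1, 0)), c(w_a = 0.75, w_g = 0.25))
  w <- adaptive_weights(runif(5), runif(5))
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("comprehensive update blends signed proposals and recovers them at unit weight", {
  popcount <- function(mask) sum(mask)
  mask <- c(1L, 0L, 1L, 0L, 0L)
  prop_a <- c(1L, 1L, 0L, 0L, 1L)
  prop_g <- c(0L, 0L, 1L, 1L, 0L)

  # W_A = 1 reproduces the ant proposal bit-for-bit after thresholding
  res <- comprehensive_update(mask, popcount(mask), prop_a, prop_g,
                              w_a = 1, w_g = 0, threshold = 0.5, popcount)
  expect_identical(res$mask, prop_a) # popcount(prop_a)=3 > 2, accepted
  # and W_G = 1 the grasshopper proposal (here popcount ties at 2: rejected)
  res_g <- comprehensive_update(mask, popcount(mask), prop_a, prop_g,
                                w_a = 0, w_g = 1, threshold = 0.5, popcount)
  expect_identical(res_g$mask, mask)

  # proposals equal to the incumbent are a fixed point
  res2 <- comprehensive_update(mask, popcount(mask), mask, mask,
                               0.6, 0.4, 0.5, popcount)
  expect_identical(res2$mask, mask)
  expect_false(res2$accepted)

  # hand-threshold check on mixed weights: x = X + 0.6*(A-X) + 0.4*(G-X)
  x <- mask + 0.6 * (prop_a - mask) + 0.4 * (prop_g - mask)
  expected <- as.integer(x > 0.5)
  res3 <- comprehensive_update(mask, -Inf, prop_a, prop_g, 0.6, 0.4, 0.5,
                               popcount)
  expect_identical(res3$mask, expected)
})

test_that("optimizer trace length, elitism and seed contract hold", {
  target <- c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 1L)
  fitness <- surrogate_fitness(target)
  ctl <- clbso_control(n_pop = 8, max_iter = 25)
  fit1 <- clbso_optimize(fitness, 8, ctl, seed = 3)
  fit2 <- clbso_optimize(fitness, 8, ctl, seed = 3)
  expect_identical(fit1, fit2)
  expect_equal(nrow(fit1$trace), 25L)
  expect_true(all(diff(fit1$trace$best_fitness) >= 0))
  expect_true(all(fit1$population %in% c(0L, 1L)))
  expect_true(all(rowSums(fit1$population) >= 1L))
  expect_true(all(fit1$pheromone >= ctl$tau_min & fit1$pheromone <= ctl$tau_max))

  fit3 <- clbso_optimize(fitness, 8, ctl, seed = 4)
  expect_false(identical(fit1$best_mask, fit3$best_mask) &&
                 identical(fit1$trace, fit3$trace))
})

test_that("weights sum to one whenever defined, across a run", {
  fitness <- surrogate_fitness(c(1L, 1L, 0L, 0L, 0L, 0L))
  fit <- clbso_optimize(fitness, 6, clbso_control(n_pop = 6, max_iter = 15),
                        seed = 9)
  defined <- !is.na(fit$trace$w_a)
  expect_true(any(defined))
  expect_true(all(abs(fit$trace$w_a[defined] + fit$trace$w_g[defined] - 1) < 1e-12))
})

test_that("disabling the comprehensive-learning phase preserves all invariants", {
  fitness <- surrogate_fitness(c(1L, 0L, 1L, 0L, 0L, 1L))
  ctl <- clbso_control(n_pop = 6, max_iter = 15, comprehensive_learning = FALSE)
  fit <- clbso_optimize(fitness, 6, ctl, seed = 2)
  expect_equal(nrow(fit$trace), 15L)
  expect_true(all(diff(fit$trace$best_fitness) >= 0))
  expect_true(all(rowSums(fit$population) >= 1L))
  expect_true(all(is.na(fit$trace$w_a)))
})

test_that("the engine never exceeds the exhaustive-search maximum", {
  set.seed(123)
  for (rep in 1:3) {
    target <- repair_mask_for_test(rbinom(7, 1, 0.4))
    fitness <- surrogate_fitness(target)
    oracle <- enumerate_best(fitness, 7)
    fit <- clbso_optimize(fitness, 7, clbso_control(n_pop = 10, max_iter = 30),
                          seed = rep)
    expect_lte(fit$best_fitness, oracle$fitness + 1e-12)
  }
})

test_that("full pipeline fit is reproducible and reports consistent fields", {
  sim <- synthetic_expression(36, 15, n_informative = 3, effect_size = 4,
                              seed = 6)
  ctl <- clbso_control(n_pop = 8, max_iter = 6)
  fit1 <- clbso(sim$dataset, classifier = centroid_classifier(), control = ctl,
                cv_folds = 4, seed = 5)
  fit2 <- clbso(sim$dataset, classifier = centroid_classifier(), control = ctl,
                cv_folds = 4, seed = 5)
  expect_identical(fit1$best_mask, fit2$best_mask)
  expect_identical(fit1$trace, fit2$trace)
  expect_equal(fit1$selected_genes,
               sim$dataset$gene_ids[which(fit1$best_mask == 1L)])
  expect_equal(fit1$best_fitness,
               0.99 * fit1$best_accuracy - 0.01 * length(fit1$selected) / 15)

  # coef returns the named indicator vector
  cf <- coef(fit1)
  expect_equal(sum(cf), length(fit1$selected))
  expect_named(cf, sim$dataset$gene_ids)

  # predictions on the test split are valid labels
  pred <- predict(fit1)
  expect_true(all(as.character(pred) %in% levels(sim$dataset$labels)))
})
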