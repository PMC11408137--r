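# Planted-signal benchmark shared by the acceptance tests.
#
# Conditions: 60 samples, 100 genes, 5 informative at effect size 2.0,
# balanced classes; objective weights 0.99/0.01 with 5-fold inner CV on the
# 60/20/20 training split; swarm of 20 run for 100 iterations. Runs are
# computed once per test session and reused across the recovery, ablation
# and stability checks.

bench_sim <- function(seed) {
  synthetic_expression(n_samples = 60, n_genes = 100, n_informative = 5,
                       effect_size = 2.0, seed = 1000 + seed)
}

bench_control <- function(comprehensive_learning = TRUE) {
  clbso_control(n_pop = 20, max_iter = 100,
                comprehensive_learning = comprehensive_learning)
}

bench_run <- function(seed, comprehensive_learning = TRUE) {
  clbso(bench_sim(seed)$dataset,
        control = bench_control(comprehensive_learning),
        cv_folds = 5, seed = seed)
}

.bench_cache <- new.env(parent = emptyenv())

bench_runs <- function(arm = c("with_cl", "without_cl"), seeds = 1:10) {
  arm <- match.arg(arm)
  key <- paste0(arm, "_", paste(range(seeds), collapse = "_"))
  hit <- get0(key, envir = .bench_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  runs <- lapply(seeds, bench_run,
                 comprehensive_learning = (arm == "with_cl"))
  names(runs) <- paste0("seed_", seeds)
  assign(key, runs, envir = .bench_cache)
  runs
}
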