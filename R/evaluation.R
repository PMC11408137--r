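#' Jaccard index of two gene sets
#'
#' `J(A, B) = |intersection| / |union|`, ranging from 0 (disjoint) to 1
#' (identical). Used to quantify run-to-run stability of selected subsets.
#'
#' @param set_a,set_b vectors of gene identifiers (duplicates ignored); not
#'   both empty.
#' @return Numeric in \[0, 1\].
#' @examples
#' jaccard_index(c("g1", "g2", "g3"), c("g2", "g3", "g4")) # 0.5
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) stop("Jaccard index undefined for two empty sets")
  length(intersect(set_a, set_b)) / u
}

#' Pairwise Jaccard matrix of a list of gene sets
#'
#' @param sets list of gene-identifier vectors.
#' @return Symmetric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  m <- diag(1, n)
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- jaccard_index(sets[[i]], sets[[j]])
  dimnames(m) <- list(names(sets), names(sets))
  m
}

#' Selection-stability analysis across seeded runs
#'
#' Re-runs the full selection pipeline once per seed (everything else held
#' fixed) and summarizes how similar the selected gene subsets are via the
#' full pairwise Jaccard matrix and its mean off-diagonal value. High values
#' mean the optimizer keeps finding the same genes rather than an arbitrary
#' equally-fit subset.
#'
#' @param ds an [expression_dataset()].
#' @param seeds two or more distinct integer seeds, one run each.
#' @param ... further arguments passed to [clbso()] (classifier, control,
#'   split, cv_folds).
#' @return A list of class `stability_report`: `sets` (selected gene sets
#'   per run), `jaccard` (pairwise matrix), `mean_jaccard` (mean of the
#'   upper triangle), `seeds`, `fits` (the run objects).
#' @export
stability_analysis <- function(ds, seeds, ...) {
  if (length(seeds) < 2L) stop("need at least 2 seeds")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  fits <- lapply(seeds, function(sd) {
    res <- tryCatch(clbso(ds, seed = sd, ...),
                    error = function(e) stop(sprintf(
                      "run with seed %d failed: %s", sd, conditionMessage(e))))
    res
  })
  sets <- lapply(fits, `[[`, "selected_genes")
  names(sets) <- paste0("seed_", seeds)
  jac <- jaccard_matrix(sets)
  structure(list(sets = sets, jaccard = jac,
                 mean_jaccard = mean(jac[upper.tri(jac)]),
                 seeds = seeds, fits = fits),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability over %d runs: mean pairwise Jaccard = %.3f\n",
              length(x$seeds), x$mean_jaccard))
  cat(sprintf("subset sizes: %s\n",
              paste(vapply(x$sets, length, integer(1L)), collapse = ", ")))
  invisible(x)
}

#' First iteration reaching a fitness threshold
#'
#' Scans a per-iteration best-fitness trace and returns the first iteration
#' whose value meets or exceeds the threshold, or `NA` if it is never
#' reached. Used to compare convergence speed across configurations.
#'
#' @param trace a numeric best-fitness vector, or a `clbso_fit` (its trace
#'   column is used).
#' @param fitness_threshold the target fitness level.
#' @return Integer iteration (1-based) or `NA_integer_`.
#' @export
convergence_iterations <- function(trace, fitness_threshold) {
  if (inherits(trace, "clbso_fit")) trace <- trace$trace$best_fitness
  trace <- as.numeric(trace)
  if (length(trace) == 0L) stop("empty trace")
  hit <- which(trace >= fitness_threshold)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Paired ablation of the comprehensive-learning phase
#'
#' For each seed, runs the pipeline twice — with and without the
#' comprehensive-learning phase — under the per-phase RNG-stream contract,
#' so within a pair every other phase draws identical random numbers. The
#' report gives per-seed best-fitness and test-accuracy differences
#' (with-CL minus without-CL), their means, and sign counts.
#'
#' @param ds an [expression_dataset()].
#' @param seeds five or more integer seeds.
#' @param control a [clbso_control()]; its `comprehensive_learning` flag is
#'   overridden per arm.
#' @param ... further arguments passed to [clbso()].
#' @return A list of class `ablation_report` with a per-seed data.frame
#'   `pairs` (columns `seed`, `fitness_with`, `fitness_without`,
#'   `fitness_diff`, `test_acc_with`, `test_acc_without`, `test_acc_diff`),
#'   plus `mean_fitness_diff`, `mean_test_acc_diff` and `sign_counts`.
#' @export
ablation_compare <- function(ds, seeds, control = clbso_control(), ...) {
  if (length(seeds) < 5L) stop("need at least 5 seeds for a paired comparison")
  ctl_on <- control; ctl_on$comprehensive_learning <- TRUE
  ctl_off <- control; ctl_off$comprehensive_learning <- FALSE
  rows <- lapply(seeds, function(sd) {
    on_fit <- clbso(ds, control = ctl_on, seed = sd, ...)
    off_fit <- clbso(ds, control = ctl_off, seed = sd, ...)
    acc_on <- final_evaluation(on_fit)$accuracy
    acc_off <- final_evaluation(off_fit)$accuracy
    data.frame(seed = sd,
               fitness_with = on_fit$best_fitness,
               fitness_without = off_fit$best_fitness,
               fitness_diff = on_fit$best_fitness - off_fit$best_fitness,
               test_acc_with = acc_on,
               test_acc_without = acc_off,
               test_acc_diff = acc_on - acc_off)
  })
  pairs <- do.call(rbind, rows)
  structure(list(
    pairs = pairs,
    mean_fitness_diff = mean(pairs$fitness_diff),
    mean_test_acc_diff = mean(pairs$test_acc_diff),
    sign_counts = c(positive = sum(pairs$fitness_diff > 0),
                    zero = sum(pairs$fitness_diff == 0),
                    negative = sum(pairs$fitness_diff < 0))
  ), class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("paired ablation over %d seeds (with CL minus without):\n",
              nrow(x$pairs)))
  cat(sprintf("  mean best-fitness difference: %+.4f\n", x$mean_fitness_diff))
  cat(sprintf("  mean test-accuracy difference: %+.4f\n", x$mean_test_acc_diff))
  cat(sprintf("  fitness-difference signs: %d positive, %d zero, %d negative\n",
              x$sign_counts[["positive"]], x$sign_counts[["zero"]],
              x$sign_counts[["negative"]]))
  invisible(x)
}

#' Final held-out evaluation of a fitted selection run
#'
#' Scores the final classifier (trained on the train, and by default
#' validation, samples restricted to the selected genes) on the untouched
#' test split. The positive class is the second factor level of the labels.
#'
#' @param fit a fitted [clbso()] object.
#' @return A `metrics_report`; see [evaluate_confusion()].
#' @export
final_evaluation <- function(fit) {
  stopifnot(inherits(fit, "clbso"))
  idx <- which(fit$split$role == "test")
  if (length(idx) == 0L) stop("the fit has no test split")
  truth <- fit$dataset$labels[idx]
  pred <- predict(fit, fit$dataset$matrix[idx, , drop = FALSE])
  evaluate_confusion(truth, pred, positive_class = levels(fit$dataset$labels)[2L])
}
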