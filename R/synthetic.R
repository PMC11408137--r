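#' Generate a synthetic two-class expression matrix with planted signal
#'
#' Emulates the structure of a two-class (e.g. tumour vs normal) expression
#' experiment at a scale where ground truth is known: a small set of
#' informative genes whose class means differ by `effect_size` noise
#' standard deviations, optional redundant genes that are noisy copies of
#' informative ones, and a background of pure standard-Gaussian noise genes.
#'
#' Informative genes are drawn with per-class means at -delta/2 and +delta/2
#' and unit variance. Each redundant gene is
#' `rho * parent + sqrt(1 - rho^2) * noise`, so its population correlation
#' with its informative parent is exactly `rho` and it carries the same
#' (attenuated) class signal. All remaining genes are standard Gaussian,
#' independent of the labels.
#'
#' @param n_samples number of samples (rows).
#' @param n_genes total number of genes (columns).
#' @param n_informative number of genes carrying the class-mean shift.
#' @param effect_size class mean difference delta, in noise-SD units.
#' @param n_redundant number of correlated copies of informative genes.
#' @param rho_dup correlation of each redundant gene with its parent.
#' @param class_balance proportion of samples in the positive class.
#' @param seed integer seed; the output is a pure function of the arguments.
#' @return A list with elements `dataset` (an [expression_dataset()] with
#'   labels `case`/`control`) and `truth` (list with `informative`,
#'   `redundant` — integer column indices — `parents`, and the generating
#'   parameters).
#' @examples
#' sim <- synthetic_expression(n_samples = 60, n_genes = 100,
#'                             n_informative = 5, effect_size = 2, seed = 1)
#' dim(sim$dataset)
#' sim$truth$informative
#' @export
synthetic_expression <- function(n_samples, n_genes, n_informative,
                                 effect_size = 2, n_redundant = 0L,
                                 rho_dup = 0.8, class_balance = 0.5,
                                 seed = 1L) {
  if (n_informative + n_redundant > n_genes)
    stop("n_informative + n_redundant must not exceed n_genes")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (rho_dup < 0 || rho_dup > 1) stop("rho_dup must be in [0, 1]")
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must be in (0, 1)")
  if (n_redundant > 0L && n_informative == 0L)
    stop("redundant genes need at least one informative parent")

  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)

  n_pos <- max(1L, min(n_samples - 1L, round(n_samples * class_balance)))
  labels <- factor(rep(c("case", "control"), c(n_pos, n_samples - n_pos)),
                   levels = c("control", "case"))
  shift <- ifelse(labels == "case", effect_size / 2, -effect_size / 2)

  mat <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  informative <- seq_len(n_informative)
  redundant <- if (n_redundant > 0L) n_informative + seq_len(n_redundant) else integer(0)
  if (n_informative > 0L)
    mat[, informative] <- mat[, informative] + shift
  parents <- integer(0)
  if (n_redundant > 0L) {
    parents <- informative[((seq_len(n_redundant) - 1L) %% n_informative) + 1L]
    mat[, redundant] <- rho_dup * mat[, parents, drop = FALSE] +
      sqrt(1 - rho_dup^2) * mat[, redundant, drop = FALSE]
  }

  ds <- expression_dataset(mat, labels)
  list(dataset = ds,
       truth = list(informative = informative,
                    redundant = redundant,
                    parents = parents,
                    informative_ids = ds$gene_ids[informative],
                    redundant_ids = ds$gene_ids[redundant],
                    params = list(n_samples = n_samples, n_genes = n_genes,
                                  n_informative = n_informative,
                                  effect_size = effect_size,
                                  n_redundant = n_redundant, rho_dup = rho_dup,
                                  class_balance = class_balance, seed = seed)))
}
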