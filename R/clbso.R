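#' Hybrid swarm gene selection for two-class expression data
#'
#' Fits the full wrapper feature-selection pipeline: the data are split
#' (stratified) into train/validation/test sets, cross-validation folds are
#' built from the training split only, and the hybrid swarm optimizer
#' maximizes `w1 * cv_accuracy - w2 * subset_size / n_genes` over binary
#' gene masks using the wrapped classifier. The optimizer never sees
#' validation or test labels. The returned object carries the selected gene
#' subset, the optimization trace, and a final classifier refitted on the
#' training (plus, optionally, validation) samples restricted to the
#' selected genes, ready for [predict()].
#'
#' @param x an [expression_dataset()], or a numeric samples x genes matrix.
#' @param labels per-sample binary labels; ignored when `x` is already an
#'   `expression_dataset`.
#' @param classifier a `classifier_adapter`; default [svm_classifier()].
#' @param control a [clbso_control()] list of optimizer parameters. The
#'   objective weights live in `control$weights`.
#' @param split length-3 train/validation/test fractions (default
#'   60/20/20). Use `c(1, 0, 0)` to optimize on all samples (no held-out
#'   reporting).
#' @param cv_folds number of inner cross-validation folds on the training
#'   split (default 10).
#' @param refit_with_validation refit the final model on train + validation
#'   (default `TRUE`; the test split is never touched).
#' @param seed master seed; the whole fit is a pure function of
#'   `(x, labels, arguments, seed)`.
#' @return An object of class `clbso`; see [clbso_optimize()] for the
#'   optimizer fields. Adds: `dataset`, `split` (a `split_assignment`),
#'   `folds`, `classifier`, `selected_genes`, `final_model`, `n_genes`.
#' @examples
#' sim <- synthetic_expression(60, 40, n_informative = 3, effect_size = 3, seed = 7)
#' fit <- clbso(sim$dataset, control = clbso_control(n_pop = 10, max_iter = 5),
#'              cv_folds = 5, seed = 7)
#' fit$selected_genes
#' @export
clbso <- function(x, labels = NULL, classifier = svm_classifier(),
                  control = clbso_control(), split = c(0.6, 0.2, 0.2),
                  cv_folds = 10L, refit_with_validation = TRUE, seed = 1L) {
  ds <- if (inherits(x, "expression_dataset")) x
        else expression_dataset(as.matrix(x), labels)
  stopifnot(inherits(control, "clbso_control"),
            inherits(classifier, "classifier_adapter"))

  assignment <- split_dataset(ds, fractions = split, stratified = TRUE,
                              seed = derive_seed(seed, "split"))
  train_idx <- which(assignment$role == "train")
  train_ds <- subset_samples(ds, train_idx)
  folds <- make_cv_folds(train_ds, k = cv_folds, stratified = TRUE,
                         seed = derive_seed(seed, "folds"))

  fitness_fn <- make_fitness(train_ds, classifier, folds,
                             weights = control$weights)
  fit <- clbso_optimize(fitness_fn, ncol(ds$matrix), control, seed)

  sel <- which(fit$best_mask == 1L)
  refit_idx <- if (refit_with_validation)
    which(assignment$role %in% c("train", "validation")) else train_idx
  final_model <- classifier$fit(ds$matrix[refit_idx, sel, drop = FALSE],
                                ds$labels[refit_idx])

  # the objective is affine in accuracy, so the trace's accuracy column can
  # be recovered exactly: acc = (f + w2 * k / n) / w1
  w <- control$weights
  fit$trace$best_accuracy <-
    (fit$trace$best_fitness + w[2L] * fit$trace$n_selected / ncol(ds$matrix)) / w[1L]
  fit$best_accuracy <- attr(fitness_fn, "accuracy")(fit$best_mask)

  structure(c(fit,
              list(dataset = ds, split = assignment, folds = folds,
                   classifier = classifier,
                   selected = sel,
                   selected_genes = ds$gene_ids[sel],
                   final_model = final_model,
                   refit_role = if (refit_with_validation)
                     c("train", "validation") else "train",
                   n_genes = ncol(ds$matrix))),
            class = c("clbso", "clbso_fit"))
}

#' @export
print.clbso <- function(x, ...) {
  cat("Hybrid swarm gene selection (CLBSO)\n")
  cat(sprintf("  %d samples x %d genes; classifier: %s\n",
              nrow(x$dataset$matrix), x$n_genes, x$classifier$label))
  cat(sprintf("  population %d, %d iterations, seed %d%s\n",
              x$control$n_pop, x$control$max_iter, x$seed,
              if (x$control$comprehensive_learning) ""
              else " (comprehensive-learning phase disabled)"))
  cat(sprintf("  selected %d genes, best fitness %.4f (cv accuracy %.4f)\n",
              length(x$selected), x$best_fitness, x$best_accuracy))
  invisible(x)
}

#' @export
summary.clbso <- function(object, ...) {
  test_metrics <- NULL
  if (any(object$split$role == "test"))
    test_metrics <- final_evaluation(object)
  out <- list(fit = object, test_metrics = test_metrics,
              n_selected = length(object$selected),
              selected_genes = object$selected_genes)
  class(out) <- "summary.clbso"
  out
}

#' @export
print.summary.clbso <- function(x, ...) {
  print(x$fit)
  genes <- x$selected_genes
  shown <- paste(utils::head(genes, 10L), collapse = ", ")
  if (length(genes) > 10L) shown <- paste0(shown, ", ...")
  cat(sprintf("  genes: %s\n", shown))
  if (!is.null(x$test_metrics)) {
    cat("held-out test performance:\n")
    print(x$test_metrics)
  }
  invisible(x)
}

#' Selected-gene indicator coefficients
#'
#' @param object a fitted [clbso()] object.
#' @param ... unused.
#' @return Named 0/1 vector over genes: 1 for selected genes.
#' @export
coef.clbso <- function(object, ...) {
  stats::setNames(object$best_mask, object$dataset$gene_ids)
}

#' Predict class labels with the final selected-subset classifier
#'
#' @param object a fitted [clbso()] object.
#' @param newdata samples x genes numeric matrix with the training genes
#'   (all of them or at least the selected ones, matched by column name
#'   when named). Defaults to the held-out test split.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.clbso <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    idx <- which(object$split$role == "test")
    if (length(idx) == 0L) stop("no test split; supply 'newdata'")
    newdata <- object$dataset$matrix[idx, , drop = FALSE]
  }
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$selected_genes %in% colnames(newdata))) {
    sub <- newdata[, object$selected_genes, drop = FALSE]
  } else if (ncol(newdata) == object$n_genes) {
    sub <- newdata[, object$selected, drop = FALSE]
  } else if (ncol(newdata) == length(object$selected)) {
    sub <- newdata
  } else {
    stop(sprintf("newdata has %d columns; expected %d genes or the %d selected genes",
                 ncol(newdata), object$n_genes, length(object$selected)))
  }
  object$classifier$predict(object$final_model, sub)
}

#' Plot the optimization trace
#'
#' Best-so-far fitness (monotone non-decreasing by construction) and the
#' size of the best subset against iteration.
#'
#' @param x a `clbso_fit` or [clbso()] object.
#' @param ... passed to [plot.default()].
#' @export
plot.clbso_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(x$trace$iteration, x$trace$best_fitness, type = "s",
       xlab = "iteration", ylab = "best fitness", ...)
  plot(x$trace$iteration, x$trace$n_selected, type = "s",
       xlab = "iteration", ylab = "genes in best subset", ...)
  invisible(x)
}
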