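#' Confusion-matrix classification metrics
#'
#' Computes accuracy, precision, recall and F-measure from true and
#' predicted labels. Accuracy is (TP + TN) / total; precision is
#' TP / (TP + FP); recall is TP / (TP + FN); the F-measure is the harmonic
#' mean 2 * Prec * Rec / (Prec + Rec). Zero-denominator cases (no predicted
#' positives, or no true positives in the truth) return 0 by convention.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_class the label counted as positive; a class absent from
#'   both vectors yields zero TP/FP/FN counts and the zero conventions
#'   above.
#' @return A list of class `metrics_report` with `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `precision`, `recall`, `f_measure`.
#' @examples
#' evaluate_confusion(c(1,1,0,0), c(1,0,1,0), positive_class = 1)
#' @export
evaluate_confusion <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred))
    stop(sprintf("label length mismatch: %d vs %d", length(y_true), length(y_pred)))
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  pos <- as.character(positive_class)
  tp <- sum(y_true == pos & y_pred == pos)
  tn <- sum(y_true != pos & y_pred != pos)
  fp <- sum(y_true != pos & y_pred == pos)
  fn <- sum(y_true == pos & y_pred != pos)
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  fm <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = acc, precision = prec, recall = rec,
                 f_measure = fm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("Acc=%.4f  Prec=%.4f  Rec=%.4f  Fm=%.4f\n",
              x$accuracy, x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Support-vector classifier adapter
#'
#' The default wrapped classifier: a support-vector machine, by default with
#' a linear kernel, fitted without internal rescaling. An adapter is a list
#' with a `fit(x, y)` and a `predict(model, x)` function; any classifier
#' honouring that contract (and deterministic given its inputs) can be
#' swapped in.
#'
#' @param kernel SVM kernel, passed to [e1071::svm()].
#' @param cost regularization constant.
#' @param ... further arguments to [e1071::svm()].
#' @return A `classifier_adapter` list with elements `fit`, `predict`,
#'   `label`.
#' @export
svm_classifier <- function(kernel = "linear", cost = 1, ...) {
  structure(list(
    # the dataset container refuses missing values at load, so the NA pass
    # inside libsvm's wrapper is redundant work; skipping it does not change
    # predictions
    fit = function(x, y) e1071::svm(x, y, kernel = kernel, cost = cost,
                                    scale = FALSE, na.action = stats::na.pass,
                                    ...),
    predict = function(model, x) stats::predict(model, x,
                                                na.action = stats::na.pass),
    label = sprintf("svm (%s kernel, cost=%g)", kernel, cost)
  ), class = "classifier_adapter")
}

#' Nearest-centroid classifier adapter
#'
#' A minimal deterministic classifier: each class is represented by its
#' per-gene mean profile and a sample is assigned to the nearer centroid in
#' Euclidean distance. Useful for fast tests and as a sanity baseline.
#'
#' @return A `classifier_adapter` list; see [svm_classifier()].
#' @export
centroid_classifier <- function() {
  structure(list(
    fit = function(x, y) {
      y <- factor(y)
      cen <- matrix(0, ncol(x), nlevels(y))
      for (j in seq_len(nlevels(y)))
        cen[, j] <- colMeans(x[y == levels(y)[j], , drop = FALSE])
      list(centroids = cen, levels = levels(y))
    },
    predict = function(model, x) {
      cen <- model$centroids # genes x classes
      d2 <- matrix(0, nrow(x), ncol(cen))
      for (j in seq_len(ncol(cen)))
        d2[, j] <- rowSums(sweep(x, 2, cen[, j])^2)
      factor(model$levels[max.col(-d2, ties.method = "first")],
             levels = model$levels)
    },
    label = "nearest centroid"
  ), class = "classifier_adapter")
}

#' Cross-validated accuracy of a classifier on a gene subset
#'
#' For each fold, trains the classifier on all other folds restricted to the
#' genes selected by `mask` and scores accuracy on the held-out fold;
#' returns the unweighted mean over folds. Deterministic given the folds and
#' the classifier.
#'
#' @param ds an [expression_dataset()].
#' @param mask binary inclusion vector of length `n_genes` with at least one
#'   selected gene.
#' @param classifier a `classifier_adapter`, e.g. [svm_classifier()].
#' @param folds a [make_cv_folds()] assignment for `ds`.
#' @return Mean held-out accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(ds, mask, classifier, folds) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(folds, "fold_assignment"))
  mask <- check_mask(mask, ncol(ds$matrix))
  x <- ds$matrix[, mask == 1L, drop = FALSE]
  y <- ds$labels
  accs <- vapply(seq_len(folds$k), function(f) {
    hold <- folds$fold == f
    model <- classifier$fit(x[!hold, , drop = FALSE], y[!hold])
    pred <- classifier$predict(model, x[hold, , drop = FALSE])
    mean(as.character(pred) == as.character(y[hold]))
  }, numeric(1L))
  mean(accs)
}

check_mask <- function(mask, n_genes) {
  mask <- as.integer(mask)
  if (length(mask) != n_genes)
    stop(sprintf("mask length %d does not match %d genes", length(mask), n_genes))
  if (!all(mask %in% c(0L, 1L))) stop("mask entries must be 0 or 1")
  if (sum(mask) == 0L)
    stop("empty mask: at least one gene must be selected (repair is the optimizer's job)")
  mask
}

#' Build the wrapper fitness function
#'
#' Returns the objective the optimizer maximizes:
#' `f(X) = w1 * accuracy(X) - w2 * n_selected(X) / n_genes`,
#' where `accuracy(X)` is the cross-validated accuracy of the wrapped
#' classifier on the genes selected by the mask `X`. The accuracy term
#' rewards predictive subsets; the penalty term breaks ties toward smaller
#' ones. Evaluations are memoized on the exact bit pattern, so re-visiting a
#' mask within a run costs one lookup rather than one cross-validation.
#'
#' @param ds the training-split [expression_dataset()] the optimizer is
#'   allowed to see.
#' @param classifier a `classifier_adapter`.
#' @param folds a [make_cv_folds()] assignment for `ds`.
#' @param weights length-2 numeric `c(w1, w2)` with `w1 > 0`, `w2 >= 0`.
#' @return A function `f(mask)` returning the scalar fitness, with
#'   attributes `n_genes` and an `accuracy(mask)` accessor used for
#'   reporting.
#' @export
make_fitness <- function(ds, classifier, folds, weights = c(0.99, 0.01)) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(weights) != 2L || weights[1L] <= 0 || weights[2L] < 0)
    stop("weights must be c(w1 > 0, w2 >= 0)")
  n_genes <- ncol(ds$matrix)
  cache <- new.env(parent = emptyenv())
  acc_of <- function(mask) {
    key <- paste(which(mask == 1L), collapse = ".")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    acc <- cv_accuracy(ds, mask, classifier, folds)
    assign(key, acc, envir = cache)
    acc
  }
  f <- function(mask) {
    mask <- check_mask(mask, n_genes)
    weights[1L] * acc_of(mask) - weights[2L] * sum(mask) / n_genes
  }
  attr(f, "n_genes") <- n_genes
  attr(f, "accuracy") <- acc_of
  attr(f, "weights") <- weights
  f
}
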