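#' Construct an expression dataset
#'
#' Bundles a numeric expression matrix (samples in rows, genes in columns)
#' with per-sample binary class labels. This is the container every other
#' function in the package consumes. Validation is strict: missing values,
#' duplicated identifiers and non-binary labels are errors, never silently
#' repaired.
#'
#' @param matrix numeric matrix, samples x genes. Row and column names, when
#'   present, seed `sample_ids` and `gene_ids`.
#' @param labels vector of per-sample class labels with exactly two distinct
#'   values; coerced to a factor.
#' @param gene_ids,sample_ids optional character identifiers; defaults are
#'   taken from dimnames or generated (`gene_1`, ..., `sample_1`, ...).
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `gene_ids`, `sample_ids`, `labels` (two-level factor).
#' @export
expression_dataset <- function(matrix, labels, gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix (samples x genes)")
  n <- nrow(matrix)
  m <- ncol(matrix)
  if (anyNA(matrix)) {
    idx <- which(is.na(matrix), arr.ind = TRUE)[1L, ]
    stop(sprintf("expression matrix contains missing values (first at row %d, column %d); impute or filter before loading",
                 idx[1L], idx[2L]))
  }
  if (length(labels) != n)
    stop(sprintf("labels length (%d) does not match number of samples (%d)",
                 length(labels), n))
  if (anyNA(labels)) stop("labels contain missing values")
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop(sprintf("labels must be binary; observed %d classes: %s",
                 nlevels(labels), paste(levels(labels), collapse = ", ")))
  if (is.null(gene_ids)) gene_ids <- colnames(matrix)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != m) stop("gene_ids length does not match number of genes")
  if (anyDuplicated(gene_ids))
    stop(sprintf("duplicate gene identifiers: %s",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (is.null(sample_ids)) sample_ids <- rownames(matrix)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length does not match number of samples")
  if (anyDuplicated(sample_ids))
    stop(sprintf("duplicate sample identifiers: %s",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  dimnames(matrix) <- list(sample_ids, gene_ids)
  structure(list(matrix = matrix, gene_ids = gene_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("expression_dataset: %d samples x %d genes\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("classes: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Subset an expression dataset by samples
#'
#' @param ds an [expression_dataset()].
#' @param samples integer, logical or character index into samples.
#' @return An `expression_dataset` restricted to the chosen samples.
#' @export
subset_samples <- function(ds, samples) {
  stopifnot(inherits(ds, "expression_dataset"))
  idx <- if (is.character(samples)) match(samples, ds$sample_ids) else samples
  expression_dataset(ds$matrix[idx, , drop = FALSE],
                     ds$labels[idx],
                     gene_ids = ds$gene_ids,
                     sample_ids = ds$sample_ids[idx])
}
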