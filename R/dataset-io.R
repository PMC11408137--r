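#' Read an expression table from a delimited text file
#'
#' Reads a CSV/TSV expression table into an [expression_dataset()]. The
#' default orientation matches CuMiDa-style exports: samples in rows, genes
#' in columns, with a class-label column in the table. A genes-in-rows table
#' is transposed on load so the in-memory convention is always
#' samples x genes. Labels may instead come from a sidecar two-column file
#' (`sample_id,label`).
#'
#' @param path path to a delimited text file with a header row.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @param label_column name of the class column when samples are in rows.
#' @param label_file optional sidecar CSV/TSV with columns `sample_id` and
#'   `label`; required when `orientation = "genes_in_rows"`.
#' @param sep field separator; `NULL` (default) sniffs comma vs tab from the
#'   header line.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_in_rows", "genes_in_rows"),
                                  label_column = "class",
                                  label_file = NULL,
                                  sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")

  labels <- NULL
  if (orientation == "samples_in_rows" && is.null(label_file)) {
    if (!label_column %in% colnames(tab))
      stop(sprintf("label column '%s' not found in %s", label_column, path))
    labels <- tab[[label_column]]
    tab <- tab[, setdiff(colnames(tab), label_column), drop = FALSE]
  }

  mat <- as.matrix(tab)
  if (!is.numeric(mat)) {
    bad <- colnames(tab)[!vapply(tab, is.numeric, logical(1L))]
    stop(sprintf("non-numeric expression columns: %s",
                 paste(bad, collapse = ", ")))
  }
  if (orientation == "genes_in_rows") mat <- t(mat)

  if (is.null(labels)) {
    if (is.null(label_file))
      stop("labels required: give 'label_column' in-table or a sidecar 'label_file'")
    lab_tab <- utils::read.table(label_file, header = TRUE, sep = sniff_sep(label_file),
                                 stringsAsFactors = FALSE)
    if (ncol(lab_tab) < 2L)
      stop("label file must have two columns: sample_id, label")
    idx <- match(rownames(mat), as.character(lab_tab[[1L]]))
    if (anyNA(idx))
      stop(sprintf("label file missing samples: %s",
                   paste(rownames(mat)[is.na(idx)], collapse = ", ")))
    labels <- lab_tab[[2L]][idx]
  }

  expression_dataset(mat, labels)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write an expression dataset to CSV
#'
#' Writes the samples x genes convention `read_expression_table()` reads by
#' default: one row per sample, gene columns, plus a `class` label column.
#'
#' @param ds an [expression_dataset()].
#' @param path output file path.
#' @param label_column name for the class column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, label_column = "class") {
  stopifnot(inherits(ds, "expression_dataset"))
  out <- data.frame(ds$matrix, check.names = FALSE)
  out[[label_column]] <- as.character(ds$labels)
  utils::write.csv(out, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Assigns each sample to one of three roles. The default 60/20/20 split
#' reserves most data for the selection run while keeping held-out sets for
#' tuning and final reporting. Stratification (default on) preserves the
#' class ratio in every role to within one sample, using largest-remainder
#' rounding per class.
#'
#' @param ds an [expression_dataset()].
#' @param fractions length-3 positive numeric summing to 1, in the order
#'   train, validation, test. Zero entries are allowed and produce empty
#'   roles.
#' @param stratified preserve per-class proportions in each role?
#' @param seed integer seed; the assignment is a pure function of
#'   `(ds, fractions, stratified, seed)`.
#' @return An object of class `split_assignment`: list with `role` (factor
#'   train/validation/test per sample, named by sample id), `fractions`,
#'   `seed`.
#' @export
split_dataset <- function(ds, fractions = c(0.6, 0.2, 0.2),
                          stratified = TRUE, seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(fractions) != 3L || any(fractions < 0) || any(fractions > 1))
    stop("fractions must be three values in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  roles <- c("train", "validation", "test")
  n <- nrow(ds$matrix)
  active <- which(fractions > 0)

  role <- character(n)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  if (stratified) {
    for (cl in levels(ds$labels)) {
      idx <- which(ds$labels == cl)
      k <- length(idx)
      if (k < length(active))
        stop(sprintf("class '%s' has %d samples, fewer than %d split roles",
                     cl, k, length(active)))
      counts <- largest_remainder(k * fractions)
      role[idx[sample.int(k)]] <- rep(roles, counts)
    }
  } else {
    counts <- largest_remainder(n * fractions)
    role[sample.int(n)] <- rep(roles, counts)
  }
  structure(list(role = stats::setNames(factor(role, levels = roles), ds$sample_ids),
                 fractions = fractions, stratified = stratified, seed = seed),
            class = "split_assignment")
}

# integer apportionment: floor everything, hand leftovers to largest remainders
largest_remainder <- function(quota) {
  base <- floor(quota)
  left <- round(sum(quota)) - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified k-fold cross-validation assignment
#'
#' @param ds an [expression_dataset()], or any two-level factor of labels.
#' @param k number of folds (default 10).
#' @param stratified keep the class ratio within each fold to +/- 1 sample?
#' @param seed integer seed; folds are a pure function of the inputs.
#' @return An object of class `fold_assignment`: list with `fold` (integer
#'   in 1..k per sample), `k`, `stratified`, `seed`.
#' @export
make_cv_folds <- function(ds, k = 10L, stratified = TRUE, seed = 1L) {
  labels <- if (inherits(ds, "expression_dataset")) ds$labels else factor(ds)
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop(sprintf("cannot make %d folds from %d samples", k, n))
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    # deal each class's shuffled samples round-robin, rotating the starting
    # fold between classes so fold sizes stay within 1 overall
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      shuffled <- idx[sample.int(length(idx))]
      fold[shuffled] <- ((offset + seq_along(shuffled) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  } else {
    fold[sample.int(n)] <- ((seq_len(n) - 1L) %% k) + 1L
  }
  structure(list(fold = fold, k = as.integer(k),
                 stratified = stratified, seed = seed),
            class = "fold_assignment")
}

#' Write the report files for a completed selection run
#'
#' Writes three files sharing a prefix: `<prefix>_genes.txt` (selected gene
#' identifiers, one per line), `<prefix>_trace.csv` (per-iteration best
#' fitness, best accuracy, subset size and adaptive weights) and
#' `<prefix>_summary.json` (parameters, seed, final metrics). The JSON
#' carries no timestamps, so identical runs produce byte-identical output.
#'
#' @param result a fitted [clbso()] object.
#' @param path_prefix path prefix for the three output files.
#' @return Named character vector of the files written, invisibly.
#' @export
write_run_report <- function(result, path_prefix) {
  stopifnot(inherits(result, "clbso"))
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  files <- c(genes = paste0(path_prefix, "_genes.txt"),
             trace = paste0(path_prefix, "_trace.csv"),
             summary = paste0(path_prefix, "_summary.json"))
  writeLines(result$selected_genes, files[["genes"]])
  utils::write.csv(result$trace, files[["trace"]], row.names = FALSE, quote = FALSE)
  summary_obj <- list(
    parameters = result$control[setdiff(names(result$control), "fitness_fn")],
    seed = result$seed,
    n_genes = result$n_genes,
    n_selected = sum(result$best_mask),
    best_fitness = result$best_fitness,
    selected_genes = result$selected_genes
  )
  jsonlite::write_json(summary_obj, files[["summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
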