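#' Labelled expression dataset
#'
#' Canonical container for a samples x genes expression matrix with one class
#' label per sample. Values must be finite numerics, gene identifiers unique,
#' and at least two classes with two samples each must be present -- the
#' minimum for class-conditional statistics and stratified resampling.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers, one per column.
#' @param labels vector of class labels, one per row. Stored as a factor whose
#'   level order is the order of first appearance (reproducible confusion
#'   matrix layout).
#' @param min_class_size minimum samples per class (default 2). Split products
#'   may legitimately carry singleton classes; internal callers relax this.
#' @return an object of class `expr_dataset` with elements `values`,
#'   `gene_ids`, `labels` (factor) and `classes` (levels).
#' @export
expression_dataset <- function(values, gene_ids = colnames(values), labels,
                               min_class_size = 2L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != number of gene columns (",
         ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(labels) != nrow(values))
    stop("labels length (", length(labels), ") != number of samples (",
         nrow(values), ")")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at sample ", bad[1], ", gene ", bad[2])
  }
  labels <- factor(as.character(labels), levels = unique(as.character(labels)))
  if (nlevels(labels) < 2)
    stop("need at least 2 distinct classes, got ", nlevels(labels))
  sizes <- table(labels)
  if (any(sizes < min_class_size))
    stop("every class needs >= ", min_class_size, " samples; class '",
         names(sizes)[which.min(sizes)], "' has ", min(sizes))
  colnames(values) <- gene_ids
  structure(
    list(values = values, gene_ids = gene_ids, labels = labels,
         classes = levels(labels)),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Expression dataset: ", nrow(x$values), " samples x ",
      ncol(x$values), " genes, ", length(x$classes), " classes (",
      paste0(x$classes, ": ", as.integer(table(x$labels)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Read a labelled expression table
#'
#' Reads a delimited text file (comma or tab, sniffed from the header line)
#' into an [expression_dataset()]. The canonical layout is samples as rows
#' with a header of gene ids plus one label column. Files shipped genes-as-rows
#' (common for microarray exports) are supported via
#' `orientation = "genes_as_rows"`: there the first column holds gene ids,
#' remaining columns are samples, and one row whose id equals `label_column`
#' carries the class labels.
#'
#' @param path file path.
#' @param label_column name of the label column (or label row id when
#'   genes-as-rows). Default `"class"`.
#' @param orientation `"samples_as_rows"` (default) or `"genes_as_rows"`.
#' @return an `expr_dataset`.
#' @export
load_expression_table <- function(path, label_column = "class",
                                  orientation = c("samples_as_rows",
                                                  "genes_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (orientation == "genes_as_rows") {
    ids <- df[[1]]
    lab_row <- which(ids == label_column)
    if (length(lab_row) != 1)
      stop("label row '", label_column, "' not found (genes-as-rows layout)")
    labels <- unname(unlist(df[lab_row, -1]))
    gene_ids <- ids[-lab_row]
    raw <- t(as.matrix(df[-lab_row, -1, drop = FALSE]))
    values <- parse_numeric_cells(raw, rownames_hint = gene_ids)
    return(expression_dataset(values, gene_ids, labels))
  }
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found; columns: ",
         paste(utils::head(names(df), 5), collapse = ", "), " ...")
  labels <- df[[label_column]]
  gene_cols <- setdiff(names(df), label_column)
  raw <- as.matrix(df[gene_cols])
  values <- parse_numeric_cells(raw, rownames_hint = gene_cols)
  expression_dataset(values, gene_cols, labels)
}

# Row subset of a validated dataset. Skips re-validation: a subset can
# legitimately hold fewer than 2 samples of a class (stratified split sides).
subset_samples <- function(dataset, idx) {
  labels <- droplevels(dataset$labels[idx])
  structure(
    list(values = dataset$values[idx, , drop = FALSE],
         gene_ids = dataset$gene_ids, labels = labels,
         classes = levels(labels)),
    class = "expr_dataset"
  )
}

# Strict cell-wise numeric parsing with a row/column-naming error.
parse_numeric_cells <- function(raw, rownames_hint = NULL) {
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (any(is.na(values) | raw == "")) {
    bad <- which(is.na(values) | raw == "", arr.ind = TRUE)[1, ]
    gene <- if (!is.null(rownames_hint)) rownames_hint[bad[2]] else bad[2]
    stop("missing or non-numeric cell at sample row ", bad[1],
         ", gene '", gene, "' (value: '", raw[bad[1], bad[2]], "')")
  }
  values
}

#' Write a labelled expression table
#'
#' Writes the dataset as delimited text readable by [load_expression_table()]
#' (samples as rows, a header of gene ids plus the label column). Round-trips
#' are lossless to the printed precision (values are written with full
#' double precision, 15 significant digits).
#'
#' @param dataset an `expr_dataset`.
#' @param path output path; extension `.tsv` selects tabs, otherwise commas.
#' @param label_column label column name to write. Default `"class"`.
#' @export
write_expression_table <- function(dataset, path, label_column = "class") {
  stopifnot(inherits(dataset, "expr_dataset"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.table::as.data.table(dataset$values)
  data.table::setnames(df, dataset$gene_ids)
  df[[label_column]] <- as.character(dataset$labels)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test sets, drawing
#' `round(class_size * test_fraction)` test samples per class (clamped so no
#' class is emptied on the training side). Same seed, same split.
#'
#' @param dataset an `expr_dataset`.
#' @param test_fraction real in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` (`expr_dataset`s) and the integer
#'   index vectors `train_idx`, `test_idx`.
#' @export
split_stratified <- function(dataset, test_fraction, seed = 1L) {
  stopifnot(inherits(dataset, "expr_dataset"),
            test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in dataset$classes) {
    idx <- which(dataset$labels == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- min(n_test, length(idx) - 1L)  # never empty a class in train
    if (length(idx) - n_test < 1L)
      stop("class '", cl, "' would be emptied in the training set")
    if (n_test > 0)
      test_idx <- c(test_idx, sort(sample(idx, n_test)))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(dataset$values)), test_idx)
  list(train = subset_samples(dataset, train_idx),
       test = subset_samples(dataset, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
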