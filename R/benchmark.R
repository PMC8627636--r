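#' Leave-one-out cross-validated accuracy
#'
#' n folds of size one on the dataset restricted to the given genes;
#' accuracy is `100 * correct / n` (a percentage). Deterministic for
#' deterministic classifiers.
#'
#' @param dataset an [expression_dataset()] with at least 3 samples.
#' @param subset non-empty character vector of gene ids.
#' @param classifier classifier spec string (`"svm"`, `"dt"`, `"knn:k=5"`).
#' @return accuracy percentage in [0, 100].
#' @export
loocv_accuracy <- function(dataset, subset, classifier = "svm") {
  stopifnot(inherits(dataset, "expr_dataset"), nrow(dataset$values) >= 3)
  if (length(subset) == 0) stop("empty gene subset")
  stopifnot(all(subset %in% dataset$gene_ids))
  x <- dataset$values[, subset, drop = FALSE]
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    pred[i] <- as.character(
      train_predict(classifier, x[-i, , drop = FALSE],
                    dataset$labels[-i], x[i, , drop = FALSE]))
  }
  100 * sum(pred == as.character(dataset$labels)) / n
}

#' Rank methods per dataset
#'
#' Rank 1 goes to the highest accuracy in each dataset row; ties receive the
#' mean of the tied rank positions. Average ranks are reported both at full
#' precision and rounded half-up to 2 decimals for display.
#'
#' @param acc complete matrix of accuracy percentages, datasets in rows,
#'   methods in columns.
#' @return list with `ranks` (matrix), `average` (named numeric) and
#'   `average_display` (2-decimal, half-up).
#' @export
rank_methods <- function(acc) {
  acc <- as.matrix(acc)
  if (anyNA(acc)) stop("accuracy table has missing cells")
  ranks <- t(apply(acc, 1, function(row) rank(-row, ties.method = "average")))
  dimnames(ranks) <- dimnames(acc)
  avg <- colMeans(ranks)
  list(ranks = ranks, average = avg, average_display = round_half_up(avg, 2))
}

#' Friedman rank test across datasets
#'
#' Nonparametric test of whether k methods differ over n datasets:
#' `chi2 = 12 n / (k (k + 1)) * sum_j (Rbar_j - (k + 1) / 2)^2`, df = k - 1,
#' with the chi-square upper tail as p value. With
#' `tie_correction = TRUE` the statistic is divided by
#' `1 - sum(t^3 - t) / (n k (k^2 - 1))` over tie groups, matching
#' [stats::friedman.test()].
#'
#' @param ranks n x k matrix of per-dataset ranks (tie-averaged).
#' @param tie_correction apply the tie correction (default FALSE).
#' @return list with `chi_square`, `df`, `p_value`.
#' @export
friedman_statistic <- function(ranks, tie_correction = FALSE) {
  ranks <- as.matrix(ranks)
  n <- nrow(ranks)
  k <- ncol(ranks)
  if (n < 2 || k < 2) stop("need at least 2 datasets and 2 methods")
  rbar <- colMeans(ranks)
  chi2 <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  if (tie_correction) {
    ties <- sum(apply(ranks, 1, function(r) {
      t <- table(r)
      sum(t^3 - t)
    }))
    corr <- 1 - ties / (n * k * (k^2 - 1))
    if (corr > 0) chi2 <- chi2 / corr
  }
  df <- k - 1
  list(chi_square = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Aggregate a multi-method benchmark
#'
#' Computes, per classifier, the per-method mean accuracies (full precision
#' and 2-decimal half-up display values), rank tables, the Friedman
#' statistic, pairwise mean-accuracy differences, and the per-method mean
#' selected-gene counts.
#'
#' @param accuracy_tables named list of datasets x methods accuracy
#'   matrices, one per classifier.
#' @param gene_counts optional datasets x methods matrix of selected-gene
#'   counts.
#' @return list of class `benchmark_summary` with elements `mean_accuracy`,
#'   `mean_accuracy_display`, `rank_tables`, `friedman`,
#'   `mean_differences`, `mean_gene_counts`, `mean_gene_counts_display`.
#' @export
summarize_benchmark <- function(accuracy_tables, gene_counts = NULL) {
  stopifnot(is.list(accuracy_tables), length(accuracy_tables) >= 1,
            !is.null(names(accuracy_tables)))
  mean_acc <- lapply(accuracy_tables, function(tab) {
    tab <- as.matrix(tab)
    if (anyNA(tab)) stop("accuracy table has missing cells")
    colMeans(tab)
  })
  rank_tables <- lapply(accuracy_tables, rank_methods)
  friedman <- lapply(rank_tables, function(rt) {
    if (nrow(rt$ranks) < 2) return(NULL)   # test undefined for one dataset
    friedman_statistic(rt$ranks)
  })
  mean_diff <- lapply(mean_acc, function(mu) outer(mu, mu, `-`))
  out <- list(
    mean_accuracy = mean_acc,
    mean_accuracy_display = lapply(mean_acc, round_half_up, digits = 2),
    rank_tables = rank_tables,
    friedman = friedman,
    mean_differences = mean_diff
  )
  if (!is.null(gene_counts)) {
    gene_counts <- as.matrix(gene_counts)
    out$mean_gene_counts <- colMeans(gene_counts)
    out$mean_gene_counts_display <- round_half_up(out$mean_gene_counts, 2)
  }
  class(out) <- "benchmark_summary"
  out
}

#' @export
print.benchmark_summary <- function(x, ...) {
  for (cl in names(x$mean_accuracy)) {
    cat(cl, "- mean accuracy (%):\n")
    print(x$mean_accuracy_display[[cl]])
    cat("  average ranks:\n")
    print(x$rank_tables[[cl]]$average_display)
    fr <- x$friedman[[cl]]
    if (!is.null(fr))
      cat(sprintf("  Friedman chi-square = %.3f, df = %d, p = %.4g\n\n",
                  fr$chi_square, fr$df, fr$p_value))
  }
  if (!is.null(x$mean_gene_counts)) {
    cat("mean selected genes:\n")
    print(x$mean_gene_counts_display)
  }
  invisible(x)
}

#' Bundled microarray benchmark tables
#'
#' Published leave-one-out accuracies (percent) of eight gene-selection
#' methods on seven microarray datasets under SVM, decision-tree and KNN
#' classifiers, plus the selected-gene counts -- the reference aggregates
#' the package's summary arithmetic reproduces. Shipped as plain TSV under
#' `inst/extdata/`.
#'
#' @return list with `accuracy` (named list of `svm`, `dt`, `knn` matrices)
#'   and `gene_counts` (matrix), datasets in rows, methods in columns.
#' @export
benchmark_tables <- function() {
  read_tab <- function(name) {
    path <- system.file("extdata", name, package = "mapsogs", mustWork = TRUE)
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df[[1]]
    m
  }
  list(
    accuracy = list(svm = read_tab("benchmark_acc_svm.tsv"),
                    dt = read_tab("benchmark_acc_dt.tsv"),
                    knn = read_tab("benchmark_acc_knn.tsv")),
    gene_counts = read_tab("benchmark_gene_counts.tsv")
  )
}
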