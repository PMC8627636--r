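#' Fisher scores of genes
#'
#' Per-gene ratio of between-class to within-class scatter,
#' `sum_k n_k (mean_k - mean)^2 / sum_k n_k var_k`, with population (1/n)
#' class variances so that the sample counts weight both sums identically.
#' Higher scores mark more class-discriminative genes. A constant gene
#' (0/0) scores 0; a gene whose classes are internally constant but have
#' different means (positive numerator over a zero denominator) is capped at
#' the sentinel `1e12` so downstream min-max normalisation stays finite.
#'
#' @param dataset an [expression_dataset()].
#' @return an object of class `fisher_scores`: list with `score` (named
#'   numeric, one entry per gene, original gene order), `class_means`
#'   (classes x genes), `class_vars` (population variances, classes x genes)
#'   and `overall_mean`.
#' @export
fisher_scores <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  x <- dataset$values
  labels <- dataset$labels
  classes <- dataset$classes
  n_k <- as.numeric(table(labels)[classes])
  class_means <- rowsum(x, labels) / n_k            # classes x genes
  sq_means <- rowsum(x^2, labels) / n_k
  class_vars <- pmax(sq_means - class_means^2, 0)   # population variance
  overall <- colMeans(x)
  num <- colSums(n_k * sweep(class_means, 2, overall)^2)
  den <- colSums(n_k * class_vars)
  score <- ifelse(den > 0, num / den, ifelse(num > 0, 1e12, 0))
  score <- pmin(score, 1e12)
  names(score) <- dataset$gene_ids
  structure(
    list(score = score, class_means = class_means, class_vars = class_vars,
         overall_mean = overall),
    class = "fisher_scores"
  )
}

#' @export
print.fisher_scores <- function(x, ...) {
  cat("Fisher scores for", length(x$score), "genes; top 5:\n")
  print(utils::head(sort(x$score, decreasing = TRUE), 5))
  invisible(x)
}

#' Filter genes by Fisher score
#'
#' Either keeps every gene whose score is at least `lambda`
#' (`mode = "threshold"`), or the `m` highest-scoring genes
#' (`mode = "top_m"`, ties broken in favour of earlier gene order). The kept
#' subset preserves the original gene order. An absolute threshold is
#' dataset-scale dependent; `top_m` is the portable default used by
#' [mapsogs()].
#'
#' @param scores a [fisher_scores()] object.
#' @param mode `"top_m"` or `"threshold"`.
#' @param value `m` (positive integer, at most the gene count) or `lambda`
#'   (non-negative real).
#' @return character vector of kept gene ids, in original order.
#' @export
filter_genes <- function(scores, mode = c("top_m", "threshold"), value) {
  mode <- match.arg(mode)
  stopifnot(inherits(scores, "fisher_scores"))
  s <- scores$score
  if (mode == "threshold") {
    stopifnot(value >= 0)
    keep <- which(s >= value)
    if (length(keep) == 0)
      stop("no gene has Fisher score >= ", value,
           "; lower lambda (max observed score: ", max(s), ")")
  } else {
    stopifnot(value >= 1, value <= length(s))
    m <- as.integer(value)
    ord <- order(-s, seq_along(s))       # ties: earlier gene wins
    keep <- sort(ord[seq_len(m)])
  }
  names(s)[keep]
}

#' Min-max normalised Fisher scores
#'
#' Maps scores to [0, 1] preserving order, for use as per-gene selection
#' probabilities in swarm initialisation and in the repair operator. If all
#' scores are equal every gene maps to 0.5 (no information, uniform
#' preference).
#'
#' @param scores a [fisher_scores()] object.
#' @return named numeric vector in [0, 1], one entry per gene.
#' @export
normalize_scores <- function(scores) {
  stopifnot(inherits(scores, "fisher_scores"))
  s <- scores$score
  rng <- range(s)
  if (rng[1] == rng[2]) return(stats::setNames(rep(0.5, length(s)), names(s)))
  (s - rng[1]) / (rng[2] - rng[1])
}
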