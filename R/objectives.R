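#' Confusion counts from label vectors
#'
#' Exact TP/FP/TN/FN counts. With two classes and a designated
#' `positive_class` the counts refer to that class; in general one-vs-rest
#' counts are kept per class (each class in turn treated as positive).
#'
#' @param true,predicted equal-length label vectors.
#' @param positive_class optional class treated as positive for the scalar
#'   binary view; defaults to none (per-class counts only).
#' @return an object of class `confusion_counts`: list with `per_class`
#'   (classes x c(TP, FP, TN, FN) matrix), `n_total`, `n_correct`,
#'   `positive_class`.
#' @export
confusion_counts <- function(true, predicted, positive_class = NULL) {
  if (length(true) != length(predicted))
    stop("label vectors differ in length (", length(true), " vs ",
         length(predicted), ")")
  true <- as.character(true)
  predicted <- as.character(predicted)
  classes <- unique(c(true, predicted))
  per_class <- t(vapply(classes, function(cl) {
    tp <- sum(true == cl & predicted == cl)
    fp <- sum(true != cl & predicted == cl)
    tn <- sum(true != cl & predicted != cl)
    fn <- sum(true == cl & predicted != cl)
    c(TP = tp, FP = fp, TN = tn, FN = fn)
  }, integer(4)))
  rownames(per_class) <- classes
  if (!is.null(positive_class) && !positive_class %in% classes)
    stop("positive_class '", positive_class, "' not among observed labels")
  structure(
    list(per_class = per_class, n_total = length(true),
         n_correct = sum(true == predicted), positive_class = positive_class),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts over", x$n_total, "predictions (",
      x$n_correct, "correct )\n")
  print(x$per_class)
  invisible(x)
}

#' Classification error
#'
#' Fraction of evaluated samples not correctly classified,
#' `(FP + FN) / (TP + FP + TN + FN)` in the binary case and
#' misclassified/total in general (the two coincide for two classes).
#'
#' @param counts a [confusion_counts()] object.
#' @return real in [0, 1].
#' @export
classification_error <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"), counts$n_total > 0)
  1 - counts$n_correct / counts$n_total
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)` for the designated positive class; without one, the
#' macro-average of the per-class one-vs-rest specificities. A class with no
#' negative samples (TN + FP = 0) contributes 1: there were no negatives to
#' misclassify.
#'
#' @param counts a [confusion_counts()] object.
#' @return real in [0, 1].
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  spec_one <- function(row) {
    denom <- row["TN"] + row["FP"]
    if (denom == 0) 1 else unname(row["TN"] / denom)
  }
  if (!is.null(counts$positive_class))
    return(spec_one(counts$per_class[counts$positive_class, ]))
  mean(apply(counts$per_class, 1, spec_one))
}

# classifier spec strings: "svm", "svm:cost=2", "dt", "knn:k=5"
parse_classifier <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  type <- parts[1]
  if (!type %in% c("svm", "dt", "knn"))
    stop("unknown classifier '", type, "' (use svm, dt or knn:k=<k>)")
  params <- list()
  if (length(parts) > 1) {
    for (kv in strsplit(parts[-1], "=", fixed = TRUE)) {
      params[[kv[1]]] <- as.numeric(kv[2])
    }
  }
  list(type = type, params = params)
}

# Fit on (train_x, train_y), predict labels for test_x.
train_predict <- function(spec, train_x, train_y, test_x) {
  cl <- parse_classifier(spec)
  train_y <- droplevels(factor(train_y))
  if (nlevels(train_y) < 2)        # degenerate fold: predict the only class
    return(factor(rep(levels(train_y), nrow(test_x)),
                  levels = levels(train_y)))
  switch(cl$type,
    svm = {
      cost <- if (!is.null(cl$params$cost)) cl$params$cost else 1
      fit <- e1071::svm(train_x, train_y, kernel = "linear", cost = cost,
                        scale = FALSE)
      stats::predict(fit, test_x)
    },
    dt = {
      df <- as.data.frame(train_x)
      names(df) <- paste0("V", seq_len(ncol(train_x)))
      df$.y <- train_y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 2,
                                                         cp = 0.01))
      nd <- as.data.frame(test_x)
      names(nd) <- paste0("V", seq_len(ncol(test_x)))
      stats::predict(fit, nd, type = "class")
    },
    knn = {
      k <- if (!is.null(cl$params$k)) as.integer(cl$params$k) else 5L
      k <- min(k, nrow(train_x))
      class::knn(train_x, test_x, train_y, k = k)
    })
}

#' Cross-validated confusion counts for a gene subset
#'
#' Stratified k-fold cross-validation of a classifier on the dataset
#' restricted to the given genes; out-of-fold predictions are pooled into
#' one set of confusion counts. If `folds` exceeds the smallest class size
#' it is reduced with a warning. Same seed, same folds, same counts.
#'
#' @param dataset an [expression_dataset()].
#' @param subset character vector of gene ids (non-empty).
#' @param classifier classifier spec string: `"svm"` (linear, cost 1),
#'   `"dt"`, or `"knn:k=5"`.
#' @param folds number of folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @return a [confusion_counts()] object.
#' @export
evaluate_subset_cv <- function(dataset, subset, classifier = "svm",
                               folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "expr_dataset"), folds >= 2)
  if (length(subset) == 0)
    stop("empty gene subset; repair or reinitialise the particle first")
  stopifnot(all(subset %in% dataset$gene_ids))
  min_class <- min(table(dataset$labels))
  if (folds > min_class) {
    warning("folds reduced from ", folds, " to smallest class size ",
            min_class)
    folds <- min_class
  }
  set.seed(seed)
  fold_of <- integer(nrow(dataset$values))
  for (cl in dataset$classes) {
    idx <- sample(which(dataset$labels == cl))
    fold_of[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  x <- dataset$values[, subset, drop = FALSE]
  pred <- character(nrow(x))
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    pred[test] <- as.character(
      train_predict(classifier, x[train, , drop = FALSE],
                    dataset$labels[train], x[test, , drop = FALSE]))
  }
  confusion_counts(dataset$labels, pred)
}

#' Five-objective fitness vector of a gene subset
#'
#' Assembles the minimisation vector steering the swarm search:
#' \describe{
#'   \item{f1}{classification error of the subset (cross-validated).}
#'   \item{f2}{summed edge centrality over unordered selected gene pairs
#'     with a retained edge -- a redundancy penalty.}
#'   \item{f3}{reciprocal of the summed node centrality of the selected
#'     genes (representativeness reward, inverted for minimisation).}
#'   \item{f4}{reciprocal specificity (false-positive penalty).}
#'   \item{f5}{subset size.}
#' }
#' f3 and f4 are guarded by `epsilon` so the vector is always finite.
#'
#' @param mask logical vector over the graph genes (at least one TRUE).
#' @param counts [confusion_counts()] for the subset.
#' @param nc node-centrality vector from [node_centrality()].
#' @param ec edge-centrality matrix from [edge_centrality()].
#' @param epsilon guard for the reciprocals (default 1e-6).
#' @return named numeric vector `c(f1, f2, f3, f4, f5)`.
#' @export
fitness_vector <- function(mask, counts, nc, ec, epsilon = 1e-6) {
  stopifnot(is.logical(mask), any(mask), length(mask) == length(nc),
            all(dim(ec) == length(mask)))
  sub_ec <- ec[mask, mask, drop = FALSE]
  c(f1 = classification_error(counts),
    f2 = sum(sub_ec[upper.tri(sub_ec)]),
    f3 = 1 / max(sum(nc[mask]), epsilon),
    f4 = 1 / max(specificity(counts), epsilon),
    f5 = sum(mask))
}
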