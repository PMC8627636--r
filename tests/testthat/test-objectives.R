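test_that("confusion counts enumerate exactly and partition n", {
  true <- c("+", "+", "+", "-", "-", "-", "-", "-", "-", "+")
  pred <- c("+", "-", "-", "-", "-", "+", "-", "-", "-", "+")
  cc <- confusion_counts(true, pred, positive_class = "+")
  expect_equal(unname(cc$per_class["+", ]), c(2L, 1L, 5L, 2L))  # TP FP TN FN
  expect_equal(sum(cc$per_class["+", ]), 10L)
  # perfect predictions
  cp <- confusion_counts(true, true, positive_class = "+")
  expect_equal(unname(cp$per_class["+", c("FP", "FN")]), c(0L, 0L))
  expect_error(confusion_counts(c("A", "B"), "A"), "differ in length")
})

test_that("classification error and specificity follow their definitions", {
  cc <- structure(list(per_class = rbind(pos = c(TP = 3, FP = 1, TN = 4, FN = 2)),
                       n_total = 10, n_correct = 7, positive_class = "pos"),
                  class = "confusion_counts")
  expect_equal(classification_error(cc), 0.3)
  spec_of <- function(tn, fp) {
    structure(list(per_class = rbind(p = c(TP = 1, FP = fp, TN = tn, FN = 1)),
                   n_total = 2 + tn + fp, n_correct = 1 + tn,
                   positive_class = "p"), class = "confusion_counts")
  }
  expect_equal(specificity(spec_of(8, 2)), 0.8)
  expect_equal(specificity(spec_of(5, 0)), 1)
  expect_equal(specificity(spec_of(0, 3)), 0)
  # no negatives at all: contributes 1 by convention
  expect_equal(specificity(spec_of(0, 0)), 1)
})

test_that("multi-class counts use one-vs-rest and macro-averaged specificity", {
  true <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  cc <- confusion_counts(true, pred)
  expect_equal(classification_error(cc), 2 / 6)
  # per class one-vs-rest specificities: a: TN 3/(3+1); b: 3/(3+1); c: 4/4
  expect_equal(specificity(cc), mean(c(3 / 4, 3 / 4, 1)))
})

test_that("cross-validated counts match an independent fold loop and are seeded", {
  sim <- generate_dataset(n_samples = 30, n_genes = 20, n_blocks = 2,
                          block_sizes = c(8, 8), n_relevant = 2, seed = 13)
  ds <- sim$dataset
  sub <- ds$gene_ids[1:6]
  cc <- evaluate_subset_cv(ds, sub, "svm", folds = 3, seed = 5)
  # independent loop: rebuild the same stratified folds, train/predict per fold
  set.seed(5)
  fold_of <- integer(30)
  for (cl in ds$classes) {
    idx <- sample(which(ds$labels == cl))
    fold_of[idx] <- rep(1:3, length.out = length(idx))
  }
  x <- ds$values[, sub]
  pred <- character(30)
  for (f in 1:3) {
    fit <- e1071::svm(x[fold_of != f, ], droplevels(ds$labels[fold_of != f]),
                      kernel = "linear", cost = 1, scale = FALSE)
    pred[fold_of == f] <- as.character(predict(fit, x[fold_of == f, ]))
  }
  ref <- confusion_counts(ds$labels, pred)
  expect_equal(cc$per_class, ref$per_class)
  expect_equal(cc$n_correct, ref$n_correct)
  # determinism and degenerate-fold warning
  expect_equal(evaluate_subset_cv(ds, sub, "svm", folds = 3, seed = 5)$per_class,
               cc$per_class)
  expect_warning(evaluate_subset_cv(ds, sub, "svm", folds = 20, seed = 1),
                 "folds reduced")
  expect_error(evaluate_subset_cv(ds, character(0)), "empty gene subset")
})

test_that("a separable gene yields zero error for all classifier specs", {
  ds <- toy_dataset()
  for (spec in c("svm", "dt", "knn:k=1")) {
    cc <- evaluate_subset_cv(ds, "sep", spec, folds = 2, seed = 3)
    expect_equal(classification_error(cc), 0)
  }
})

test_that("fitness vector assembles the five objectives componentwise", {
  nc <- c(G1 = 1, G2 = 0.5, G3 = 0.2, G4 = 0, G5 = 0.8)
  ec <- matrix(0, 5, 5, dimnames = list(names(nc), names(nc)))
  ec["G1", "G2"] <- ec["G2", "G1"] <- 0.9
  ec["G1", "G5"] <- ec["G5", "G1"] <- 0.4
  cc <- structure(list(per_class = rbind(p = c(TP = 4, FP = 1, TN = 4, FN = 1)),
                       n_total = 10, n_correct = 8, positive_class = "p"),
                  class = "confusion_counts")
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  fv <- fitness_vector(mask, cc, nc, ec)
  expect_equal(unname(fv),
               c(0.2, 0.9 + 0.4, 1 / (1 + 0.5 + 0.8), 1 / 0.8, 3))
  # singleton subset: no pairs, f2 = 0
  fv1 <- fitness_vector(c(TRUE, FALSE, FALSE, FALSE, FALSE), cc, nc, ec)
  expect_equal(unname(fv1["f2"]), 0)
  expect_equal(unname(fv1["f5"]), 1)
  # epsilon guard keeps f3 finite when node centralities sum to zero
  fv0 <- fitness_vector(c(FALSE, FALSE, FALSE, TRUE, FALSE), cc, nc, ec)
  expect_true(is.finite(fv0["f3"]))
})

test_that("adding genes never decreases f2 or f5 and never increases f3", {
  set.seed(77)
  nc <- runif(10); names(nc) <- paste0("G", 1:10)
  ec <- matrix(runif(100, 0, 0.5), 10, 10)
  ec <- (ec + t(ec)) / 2; diag(ec) <- 0
  dimnames(ec) <- list(names(nc), names(nc))
  cc <- structure(list(per_class = rbind(p = c(TP = 5, FP = 0, TN = 5, FN = 0)),
                       n_total = 10, n_correct = 10, positive_class = "p"),
                  class = "confusion_counts")
  for (rep in 1:20) {
    mask <- runif(10) < 0.4
    if (!any(mask)) mask[1] <- TRUE
    bigger <- mask
    bigger[sample(which(!mask), 1)] <- TRUE
    a <- fitness_vector(mask, cc, nc, ec)
    b <- fitness_vector(bigger, cc, nc, ec)
    expect_gte(b["f2"], a["f2"])
    expect_lte(b["f3"], a["f3"])
    expect_gt(b["f5"], a["f5"])
  }
})
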