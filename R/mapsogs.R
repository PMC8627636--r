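#' Control parameters for the gene-selection search
#'
#' Collects and validates every tunable of [mapsogs()].
#'
#' @param filter_mode `"top_m"` (keep the m best Fisher scores; portable
#'   default) or `"threshold"` (keep scores >= `lambda`; scale-dependent).
#' @param top_m genes kept by the filter; capped at the gene count.
#' @param lambda Fisher-score threshold (non-negative), used when
#'   `filter_mode = "threshold"`.
#' @param theta edge-weight threshold in [0, 1] applied to the normalised
#'   similarity graph. Default 0.6: beyond it thresholding starts to cost
#'   accuracy while lower values merge clusters.
#' @param omega required selected genes per cluster for the repair operator;
#'   1 guarantees every co-expression cluster a representative.
#' @param swarm_size number of particles.
#' @param max_iterations swarm iterations cap.
#' @param inertia_w inertia weight, constrained to [0.5, 0.9].
#' @param c1,c2 cognitive/social acceleration constants (positive).
#' @param v_max velocity clamp (positive).
#' @param archive_capacity Pareto archive bound.
#' @param cv_folds stratified folds for fitness evaluation (>= 2).
#' @param classifier classifier spec for fitness: `"svm"`, `"dt"`,
#'   `"knn:k=5"`.
#' @param seed integer seed; a run is a pure function of data and control.
#' @param epsilon guard for reciprocal objectives.
#' @param node_centrality_measure `"eigenvector"` or `"strength"`.
#' @param edge_centrality_measure `"weight"` or `"betweenness"`.
#' @param transfer binarisation of the velocity update: `"vshape"` (flip
#'   with probability `|tanh(v)|`; position-stable, sustains sparse masks;
#'   default) or `"sigmoid"` (resample at `sigmoid(v)`; the classical rule,
#'   which cannot hold small subsets -- see [update_particle()]).
#' @param repair enable the cluster-coverage repair operator.
#' @param debug assert archive nondomination every iteration (slow).
#' @return a list of class `mapsogs_control`.
#' @export
mapsogs_control <- function(filter_mode = c("top_m", "threshold"),
                            top_m = 300L, lambda = 0,
                            theta = 0.6, omega = 1L,
                            swarm_size = 30L, max_iterations = 100L,
                            inertia_w = 0.7, c1 = 2, c2 = 2, v_max = 4,
                            archive_capacity = 50L, cv_folds = 5L,
                            classifier = "svm", seed = 1L, epsilon = 1e-6,
                            node_centrality_measure = c("eigenvector",
                                                        "strength"),
                            edge_centrality_measure = c("weight",
                                                        "betweenness"),
                            transfer = c("vshape", "sigmoid"),
                            repair = TRUE, debug = FALSE) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(top_m >= 1, lambda >= 0, theta >= 0, theta <= 1, omega >= 0,
            swarm_size >= 2, max_iterations >= 1,
            inertia_w >= 0.5, inertia_w <= 0.9,
            c1 > 0, c2 > 0, v_max > 0, archive_capacity >= 1,
            cv_folds >= 2, epsilon > 0)
  parse_classifier(classifier)  # fail fast on bad spec strings
  structure(
    list(filter_mode = filter_mode, top_m = as.integer(top_m),
         lambda = lambda, theta = theta, omega = as.integer(omega),
         swarm_size = as.integer(swarm_size),
         max_iterations = as.integer(max_iterations),
         inertia_w = inertia_w, c1 = c1, c2 = c2, v_max = v_max,
         archive_capacity = as.integer(archive_capacity),
         cv_folds = as.integer(cv_folds), classifier = classifier,
         seed = as.integer(seed), epsilon = epsilon,
         node_centrality_measure = match.arg(node_centrality_measure),
         edge_centrality_measure = match.arg(edge_centrality_measure),
         transfer = match.arg(transfer),
         repair = isTRUE(repair), debug = isTRUE(debug)),
    class = "mapsogs_control"
  )
}

#' Graph-guided many-objective gene selection
#'
#' Selects a small, diverse, discriminative gene subset from a labelled
#' expression matrix. The pipeline: (1) rank genes by Fisher score and keep
#' the most discriminative ones; (2) build a gene similarity graph from
#' absolute Pearson correlations, sigmoid-normalised and thresholded at
#' `theta`; (3) cluster the graph with Louvain modularity optimisation;
#' (4) run a binary particle swarm minimising five objectives
#' (cross-validated classification error, summed edge centrality of selected
#' pairs, reciprocal summed node centrality, reciprocal specificity, subset
#' size) under Pareto dominance with a bounded crowding-pruned archive. A
#' repair operator keeps every cluster represented by at least `omega`
#' selected genes, spreading the subset across co-expression clusters. The
#' returned subset is the archive member with the lowest classification
#' error (ties: smaller, then more specific).
#'
#' @param x samples x genes numeric matrix (or data.frame), an
#'   [expression_dataset()], or a formula `class ~ .` with `data`.
#' @param ... passed to methods.
#' @return an object of class `mapsogs`; see Details. Key elements:
#'   `selected` (gene ids), `archive`, `trace` (per-iteration best error and
#'   archive size), `clustering`, `fisher`, `filtered_genes`, `control`.
#' @examples
#' sim <- generate_dataset(n_samples = 40, n_genes = 30, n_blocks = 2,
#'                         block_sizes = c(10, 10), n_relevant = 2, seed = 7)
#' fit <- mapsogs(sim$dataset,
#'                control = mapsogs_control(max_iterations = 5,
#'                                          swarm_size = 10, seed = 7))
#' fit$selected
#' @export
mapsogs <- function(x, ...) UseMethod("mapsogs")

#' @rdname mapsogs
#' @param labels class label per sample (for the matrix interface).
#' @param control a [mapsogs_control()] list.
#' @export
mapsogs.default <- function(x, labels, control = mapsogs_control(), ...) {
  mapsogs_fit(expression_dataset(as.matrix(x), colnames(x), labels), control,
              match.call())
}

#' @rdname mapsogs
#' @export
mapsogs.expr_dataset <- function(x, control = mapsogs_control(), ...) {
  mapsogs_fit(x, control, match.call())
}

#' @rdname mapsogs
#' @param formula a formula whose left side names the label column of `data`;
#'   the right side must be `.` (all remaining columns are genes).
#' @param data data.frame holding gene columns and the label column.
#' @export
mapsogs.formula <- function(x, data, control = mapsogs_control(), ...) {
  label_col <- all.vars(x[[2]])
  if (length(label_col) != 1 || !label_col %in% names(data))
    stop("formula must be of the form <label column> ~ .")
  gene_cols <- setdiff(names(data), label_col)
  mapsogs_fit(expression_dataset(as.matrix(data[gene_cols]), gene_cols,
                                 data[[label_col]]),
              control, match.call())
}

# stratified fold assignment; assumes the RNG is already positioned
make_folds <- function(labels, folds) {
  fold_of <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold_of
}

# pooled out-of-fold confusion counts for fixed folds (no reseeding)
cv_counts <- function(x, labels, fold_of, classifier) {
  pred <- character(nrow(x))
  for (f in unique(fold_of)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    pred[test] <- as.character(
      train_predict(classifier, x[train, , drop = FALSE], labels[train],
                    x[test, , drop = FALSE]))
  }
  confusion_counts(labels, pred)
}

assert_nondominated <- function(archive) {
  n <- length(archive)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && dominates(archive[[i]]$fitness, archive[[j]]$fitness))
      stop("archive invariant violated: member ", i, " dominates ", j)
  }
  invisible(TRUE)
}

mapsogs_fit <- function(dataset, control, call = sys.call(-1)) {
  stopifnot(inherits(dataset, "expr_dataset"),
            inherits(control, "mapsogs_control"))
  set.seed(control$seed)

  # -- filter
  fs <- fisher_scores(dataset)
  kept <- if (control$filter_mode == "top_m") {
    filter_genes(fs, "top_m", min(control$top_m, length(fs$score)))
  } else {
    filter_genes(fs, "threshold", control$lambda)
  }
  if (length(kept) < 2)
    stop("need at least 2 genes after filtering, got ", length(kept))

  # -- graph, centralities, clusters (computed once, before the swarm loop)
  graph <- apply_edge_threshold(
    normalize_similarities(pearson_similarity_matrix(dataset, kept)),
    control$theta)
  nc <- node_centrality(graph, control$node_centrality_measure)
  ec <- edge_centrality(graph, control$edge_centrality_measure)
  clustering <- suppressWarnings(louvain(graph))
  membership <- unname(clustering$membership)
  fisher_kept <- fs$score[kept]
  probs <- pmin(0.95, pmax(0.05, normalize_scores(fs)[kept]))

  # -- swarm state
  n_genes <- length(kept)
  swarm <- initialize_swarm(control$swarm_size, probs)
  fold_of <- make_folds(dataset$labels, min(control$cv_folds,
                                            min(table(dataset$labels))))
  x_kept <- dataset$values[, kept, drop = FALSE]
  cache <- new.env(parent = emptyenv())
  evaluate <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    counts <- cv_counts(x_kept[, mask, drop = FALSE], dataset$labels,
                        fold_of, control$classifier)
    fv <- fitness_vector(mask, counts, nc, ec, control$epsilon)
    cache[[key]] <- fv
    fv
  }

  pbest_mask <- swarm$positions
  pbest_fit <- matrix(NA_real_, control$swarm_size, 5)
  archive <- list()
  trace <- data.frame(iteration = integer(0), best_f1 = numeric(0),
                      archive_size = integer(0))

  for (iter in seq_len(control$max_iterations)) {
    for (i in seq_len(control$swarm_size)) {
      mask <- swarm$positions[i, ]
      if (control$repair)
        mask <- repair(mask, membership, fisher_kept, control$omega)
      swarm$positions[i, ] <- mask
      fv <- evaluate(mask)
      if (anyNA(pbest_fit[i, ]) || dominates(fv, pbest_fit[i, ])) {
        pbest_fit[i, ] <- fv
        pbest_mask[i, ] <- mask
      } else if (!dominates(pbest_fit[i, ], fv) &&
                 !identical(unname(fv), unname(pbest_fit[i, ])) &&
                 stats::runif(1) < 0.5) {
        pbest_fit[i, ] <- fv
        pbest_mask[i, ] <- mask
      }
      archive <- update_archive(archive, mask, fv, control$archive_capacity)
    }
    if (control$debug) assert_nondominated(archive)
    fmat <- do.call(rbind, lapply(archive, `[[`, "fitness"))
    trace <- rbind(trace, data.frame(iteration = iter,
                                     best_f1 = min(fmat[, 1]),
                                     archive_size = length(archive)))
    old_positions <- swarm$positions
    for (i in seq_len(control$swarm_size)) {
      gbest <- select_gbest(archive)
      upd <- update_particle(swarm$positions[i, ], swarm$velocities[i, ],
                             pbest_mask[i, ], gbest,
                             control$inertia_w, control$c1, control$c2,
                             control$v_max, probs, control$transfer)
      swarm$positions[i, ] <- upd$position
      swarm$velocities[i, ] <- upd$velocity
    }
    if (identical(swarm$positions, old_positions)) break
  }

  best <- final_solution(archive)
  structure(
    list(call = call,
         selected = kept[best$mask],
         mask = stats::setNames(best$mask, kept),
         fitness = best$fitness,
         archive = archive,
         trace = trace,
         fisher = fs,
         filtered_genes = kept,
         graph = graph,
         node_centrality = nc,
         clustering = clustering,
         control = control,
         labels = dataset$labels,
         training = dataset),
    class = "mapsogs"
  )
}

#' @export
print.mapsogs <- function(x, ...) {
  cat("Many-objective graph-guided gene selection\n\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(length(x$filtered_genes), "genes after Fisher filtering,",
      x$clustering$k, "clusters (Q =",
      round(x$clustering$modularity, 3), ")\n")
  cat("Selected", length(x$selected), "genes:",
      paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("CV error %.4f | specificity %.4f | archive size %d\n",
              x$fitness[1], 1 / x$fitness[4], length(x$archive)))
  invisible(x)
}

#' @export
summary.mapsogs <- function(object, ...) {
  sel <- object$selected
  tab <- data.frame(
    gene_id = sel,
    fisher_score = unname(object$fisher$score[sel]),
    cluster = unname(object$clustering$membership[sel]),
    node_centrality = unname(object$node_centrality[sel])
  )
  tab <- tab[order(-tab$fisher_score), ]
  rownames(tab) <- NULL
  out <- list(selected = tab, fitness = object$fitness,
              n_filtered = length(object$filtered_genes),
              n_clusters = object$clustering$k,
              modularity = object$clustering$modularity,
              iterations = nrow(object$trace),
              control = object$control)
  class(out) <- "summary.mapsogs"
  out
}

#' @export
print.summary.mapsogs <- function(x, ...) {
  cat("Selected genes (", nrow(x$selected), " of ", x$n_filtered,
      " filtered; ", x$n_clusters, " clusters, Q = ",
      round(x$modularity, 3), "; ", x$iterations, " iterations):\n\n",
      sep = "")
  print(x$selected, digits = 4)
  cat("\nObjectives (minimised): f1 error = ", round(x$fitness[1], 4),
      ", f2 edge centrality = ", round(x$fitness[2], 4),
      ", f3 1/node centrality = ", round(x$fitness[3], 4),
      ", f4 1/specificity = ", round(x$fitness[4], 4),
      ", f5 size = ", x$fitness[5], "\n", sep = "")
  invisible(x)
}

#' Convergence trace plot
#'
#' Best archive classification error per iteration (non-increasing by
#' construction: the error-minimal archive member is crowding-protected).
#'
#' @param x a fitted `mapsogs` object.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.mapsogs <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$best_f1, type = "s",
                 xlab = "iteration", ylab = "best classification error (f1)",
                 main = "Swarm convergence", ...)
  invisible(x)
}

#' Predict class labels with the selected genes
#'
#' Trains the control's classifier on the full training data restricted to
#' the selected genes, then predicts `newdata`.
#'
#' @param object a fitted `mapsogs` object.
#' @param newdata samples x genes matrix or data.frame containing at least
#'   the selected genes (columns matched by name), or an
#'   [expression_dataset()].
#' @param ... ignored.
#' @return factor of predicted class labels.
#' @export
predict.mapsogs <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_dataset")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$selected, colnames(newdata))
  if (length(missing) > 0)
    stop("newdata lacks selected genes: ", paste(missing, collapse = ", "))
  train_predict(object$control$classifier,
                object$training$values[, object$selected, drop = FALSE],
                object$labels,
                newdata[, object$selected, drop = FALSE])
}
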