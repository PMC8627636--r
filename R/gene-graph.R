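#' Absolute Pearson similarity between genes
#'
#' Raw similarity `w_ij = |cor(gene_i, gene_j)|` across samples, in [0, 1].
#' Genes with zero variance have undefined correlation and are assigned
#' similarity 0 to every other gene (they carry no co-expression signal).
#' The diagonal is 1 but is never used as an edge.
#'
#' @param dataset an [expression_dataset()].
#' @param subset character vector of gene ids (default: all genes).
#' @return symmetric numeric matrix with gene ids as dimnames.
#' @export
pearson_similarity_matrix <- function(dataset, subset = dataset$gene_ids) {
  stopifnot(inherits(dataset, "expr_dataset"), length(subset) >= 1,
            all(subset %in% dataset$gene_ids))
  x <- dataset$values[, subset, drop = FALSE]
  w <- abs(suppressWarnings(stats::cor(x)))
  w[is.na(w)] <- 0           # zero-variance genes
  diag(w) <- 1
  dimnames(w) <- list(subset, subset)
  w
}

#' Sigmoid-normalised weighted gene graph
#'
#' Centres the raw similarities on their mean and rescales by their standard
#' deviation through a logistic squashing,
#' `w_hat = 1 / (1 + exp(-(w - mean) / sd))`, mapping all edge weights into
#' (0, 1) while preserving their order. Mean and sd are taken over all
#' unordered gene pairs i < j. If the similarities are all identical
#' (sd = 0) every edge maps to 0.5.
#'
#' @param raw symmetric raw similarity matrix from
#'   [pearson_similarity_matrix()].
#' @return an object of class `gene_graph`: list with `gene_ids`, `weights`
#'   (symmetric matrix, zero diagonal, zero = no edge), `raw_mean`, `raw_sd`
#'   and `theta` (threshold already applied; 0 until
#'   [apply_edge_threshold()]).
#' @export
normalize_similarities <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw), nrow(raw) >= 2)
  ids <- rownames(raw)
  pairs <- raw[upper.tri(raw)]
  w_bar <- mean(pairs)
  sigma <- stats::sd(pairs)
  w_hat <- if (is.na(sigma) || sigma == 0) {
    matrix(0.5, nrow(raw), ncol(raw))
  } else {
    sigmoid((raw - w_bar) / sigma)
  }
  diag(w_hat) <- 0
  dimnames(w_hat) <- list(ids, ids)
  structure(
    list(gene_ids = ids, weights = w_hat, raw_mean = w_bar,
         raw_sd = if (is.na(sigma)) 0 else sigma, theta = 0),
    class = "gene_graph"
  )
}

#' Drop weak edges
#'
#' Removes every edge whose normalised weight is below `theta` (keep rule:
#' `w_hat >= theta`). Nodes are never removed; they may become isolated.
#' Idempotent for a fixed `theta`.
#'
#' @param graph a `gene_graph`.
#' @param theta threshold in [0, 1].
#' @return the thresholded `gene_graph`.
#' @export
apply_edge_threshold <- function(graph, theta) {
  stopifnot(inherits(graph, "gene_graph"), theta >= 0, theta <= 1)
  w <- graph$weights
  w[w < theta] <- 0
  graph$weights <- w
  graph$theta <- max(graph$theta, theta)
  graph
}

#' @export
print.gene_graph <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("Weighted gene graph: ", length(x$gene_ids), " nodes, ", n_edges,
      " edges (theta = ", x$theta, ")\n", sep = "")
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node centrality of graph genes
#'
#' Influence of each gene in the thresholded co-expression graph,
#' max-normalised to [0, 1]. The default is weighted eigenvector centrality;
#' `"strength"` (sum of incident edge weights) is the alternative and the
#' automatic fallback if the eigenvector iteration fails to converge (a
#' warning is issued). Isolated nodes score 0. The sum of selected genes'
#' node centralities enters the search as a diversity/representativeness
#' reward (minimised as its reciprocal).
#'
#' @param graph a `gene_graph`.
#' @param measure `"eigenvector"` or `"strength"`.
#' @return named numeric vector in [0, 1] covering all graph nodes.
#' @export
node_centrality <- function(graph, measure = c("eigenvector", "strength")) {
  measure <- match.arg(measure)
  stopifnot(inherits(graph, "gene_graph"))
  strength <- rowSums(graph$weights)
  if (all(strength == 0))
    return(stats::setNames(rep(0, length(graph$gene_ids)), graph$gene_ids))
  nc <- if (measure == "eigenvector") {
    g <- as_igraph(graph)
    ev <- tryCatch(
      igraph::eigen_centrality(g, weights = igraph::E(g)$weight,
                               scale = TRUE)$vector,
      error = function(e) NULL)
    if (is.null(ev)) {
      warning("eigenvector centrality did not converge; using strength")
      strength
    } else ev
  } else {
    strength
  }
  nc[strength == 0] <- 0
  if (max(nc) > 0) nc <- nc / max(nc)
  stats::setNames(as.numeric(nc), graph$gene_ids)
}

#' Edge centrality of gene pairs
#'
#' Relevancy intensity per retained edge. The default measure is the
#' normalised edge weight itself (`"weight"`), which makes the summed edge
#' centrality of a selected subset a direct redundancy penalty. The
#' alternative, `"betweenness"`, is weighted edge betweenness (shortest
#' paths with distance `1/w_hat`), normalised by the number of node pairs.
#' Pairs without a retained edge have centrality 0.
#'
#' @param graph a `gene_graph`.
#' @param measure `"weight"` or `"betweenness"`.
#' @return symmetric matrix of edge centralities (0 where no edge).
#' @export
edge_centrality <- function(graph, measure = c("weight", "betweenness")) {
  measure <- match.arg(measure)
  stopifnot(inherits(graph, "gene_graph"))
  if (measure == "weight") return(graph$weights)
  g <- as_igraph(graph)
  n <- length(graph$gene_ids)
  ec <- matrix(0, n, n, dimnames = list(graph$gene_ids, graph$gene_ids))
  if (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, weights = 1 / igraph::E(g)$weight)
    eb <- eb / choose(n, 2)
    ends <- igraph::ends(g, igraph::E(g))
    for (k in seq_along(eb)) {
      ec[ends[k, 1], ends[k, 2]] <- eb[k]
      ec[ends[k, 2], ends[k, 1]] <- eb[k]
    }
  }
  ec
}
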