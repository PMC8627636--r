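#' Weighted Newman-Girvan modularity
#'
#' Quality of a gene partition: the fraction of edge weight inside clusters
#' minus its expectation under a degree-preserving null model,
#' `Q = sum_c [ W_c / (2m) - (K_c / (2m))^2 ]` with `W_c` twice the
#' intra-cluster weight, `K_c` the summed node strength of cluster c and `m`
#' the total edge weight. Q lies in [-0.5, 1]. An edgeless graph (m = 0)
#' has Q defined as 0.
#'
#' @param graph a `gene_graph`.
#' @param membership integer cluster index per node (graph order or named).
#' @return a single number.
#' @export
modularity_q <- function(graph, membership) {
  stopifnot(inherits(graph, "gene_graph"))
  membership <- align_membership(graph, membership)
  W <- graph$weights
  m <- sum(W) / 2
  if (m == 0) return(0)
  k <- rowSums(W)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    w_c <- sum(W[idx, idx, drop = FALSE])          # counts each edge twice
    k_c <- sum(k[idx])
    q <- q + w_c / (2 * m) - (k_c / (2 * m))^2
  }
  q
}

align_membership <- function(graph, membership) {
  if (!is.null(names(membership))) {
    if (!all(graph$gene_ids %in% names(membership)))
      stop("membership does not cover all graph nodes")
    membership <- membership[graph$gene_ids]
  }
  if (length(membership) != length(graph$gene_ids) || anyNA(membership))
    stop("membership must assign every graph node a cluster")
  as.integer(membership)
}

#' Modularity gain of inserting a node into a cluster
#'
#' The change in modularity when node `node` (currently outside every
#' cluster, i.e. removed from its own community first, the standard Louvain
#' bookkeeping) is inserted into `target`:
#' `dQ = k_iin / m - sigma_tot * k_i / (2 m^2)` where `k_iin` is the weight
#' between the node and the target's members, `sigma_tot` the summed strength
#' of the target's members and `k_i` the node's strength. This equals the
#' full-formula modularity difference between the node-in-target and
#' node-as-singleton partitions exactly.
#'
#' @param graph a `gene_graph`.
#' @param membership cluster index per node; the entry for `node` is ignored
#'   (the node is treated as removed).
#' @param node node index or gene id.
#' @param target cluster index to insert into.
#' @return the modularity change (a single number).
#' @export
modularity_gain <- function(graph, membership, node, target) {
  stopifnot(inherits(graph, "gene_graph"))
  membership <- align_membership(graph, membership)
  if (is.character(node)) node <- match(node, graph$gene_ids)
  if (is.na(node) || node < 1 || node > length(graph$gene_ids))
    stop("unknown node")
  W <- graph$weights
  m <- sum(W) / 2
  if (m == 0) return(0)
  members <- setdiff(which(membership == target), node)
  if (length(members) == 0 && !any(membership[-node] == target))
    stop("unknown target cluster: ", target)
  k_i <- sum(W[node, ])
  k_iin <- sum(W[node, members])
  sigma_tot <- sum(rowSums(W)[members])
  k_iin / m - sigma_tot * k_i / (2 * m^2)
}

# One Louvain local-moving pass over an adjacency matrix B (self-loops on the
# diagonal count once toward strength). Returns the community of each node.
louvain_local_moves <- function(B) {
  nb <- nrow(B)
  k <- rowSums(B)
  m <- sum(B) / 2
  comm <- seq_len(nb)
  sigma_tot <- k                                   # one node per community
  visit <- sample.int(nb)
  tol <- 1e-12
  repeat {
    moved <- FALSE
    for (i in visit) {
      ci <- comm[i]
      sigma_tot[ci] <- sigma_tot[ci] - k[i]        # remove i
      nbrs <- which(B[i, ] > 0)
      nbrs <- nbrs[nbrs != i]
      k_iin <- rep(0, 0)
      if (length(nbrs) > 0)
        k_iin <- vapply(split(B[i, nbrs], comm[nbrs]), sum, numeric(1))
      cand <- sort(unique(c(ci, as.integer(names(k_iin)))))
      gain <- vapply(cand, function(cc) {
        kin <- if (as.character(cc) %in% names(k_iin))
          k_iin[[as.character(cc)]] else 0
        kin / m - sigma_tot[cc] * k[i] / (2 * m^2)
      }, numeric(1))
      best <- cand[which.max(gain > max(gain) - tol)]  # ties: lowest index
      comm[i] <- best
      sigma_tot[best] <- sigma_tot[best] + k[i]
      if (best != ci) moved <- TRUE
    }
    if (!moved) break
  }
  comm
}

#' Louvain clustering of the gene graph
#'
#' Two-phase Louvain: greedy local moves maximising the modularity gain
#' (ties broken towards the lowest cluster index), then aggregation of
#' clusters into super-nodes, repeated until the partition no longer
#' changes. Node visit order is shuffled, so the result is deterministic
#' given `seed`. Isolated nodes end as singleton clusters. If thresholding
#' removed every edge, every node becomes a singleton and a warning is
#' issued (downstream cluster-coverage repair then degenerates gracefully).
#'
#' @param graph a `gene_graph`.
#' @param seed integer seed for the visit order, or NULL to use the current
#'   RNG state.
#' @return an object of class `gene_clustering`: list with `membership`
#'   (named integer vector, clusters numbered 1..k by first appearance in
#'   gene order), `k`, `modularity`, and `q_history` (modularity after each
#'   aggregation level, non-decreasing).
#' @export
louvain <- function(graph, seed = NULL) {
  stopifnot(inherits(graph, "gene_graph"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(graph$gene_ids)
  W <- graph$weights
  if (sum(W) == 0) {
    warning("graph has no edges after thresholding; every gene is a singleton cluster")
    membership <- stats::setNames(seq_len(n), graph$gene_ids)
    return(structure(list(membership = membership, k = n, modularity = 0,
                          q_history = 0), class = "gene_clustering"))
  }
  assign <- seq_len(n)      # original node -> current super-node
  B <- W
  q_history <- numeric(0)
  repeat {
    comm <- louvain_local_moves(B)
    comm <- match(comm, unique(comm))              # relabel 1..K
    assign <- comm[assign]
    q_history <- c(q_history, modularity_q(graph, assign))
    if (length(unique(comm)) == nrow(B)) break     # fixed point
    # aggregate clusters into super-nodes
    B <- rowsum(t(rowsum(B, comm)), comm)
  }
  # stable labels: renumber by first appearance in original gene order
  membership <- match(assign, unique(assign))
  names(membership) <- graph$gene_ids
  structure(
    list(membership = membership, k = length(unique(membership)),
         modularity = q_history[length(q_history)], q_history = q_history),
    class = "gene_clustering"
  )
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat("Gene clustering: ", x$k, " clusters, modularity Q = ",
      round(x$modularity, 4), "\n", sep = "")
  print(table(cluster = x$membership))
  invisible(x)
}
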