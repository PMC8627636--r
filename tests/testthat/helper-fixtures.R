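# Shared fixture builders; everything generated in code.

# 8-sample, 3-gene dataset with a perfectly separating first gene.
toy_dataset <- function() {
  expression_dataset(
    values = cbind(
      sep   = c(0, 1, 0.5, 0.2, 10, 11, 10.5, 10.2),
      flat  = rep(2, 8),
      noise = c(5, 3, 4, 6, 5, 3, 4, 6)
    ),
    gene_ids = c("sep", "flat", "noise"),
    labels = rep(c("A", "B"), each = 4)
  )
}

# gene_graph straight from a symmetric weight matrix (diag zeroed).
graph_from_weights <- function(W, theta = 0) {
  ids <- rownames(W)
  if (is.null(ids)) {
    ids <- paste0("G", seq_len(nrow(W)))
    dimnames(W) <- list(ids, ids)
  }
  diag(W) <- 0
  structure(list(gene_ids = ids, weights = W, raw_mean = mean(W),
                 raw_sd = stats::sd(W), theta = theta),
            class = "gene_graph")
}

# random symmetric weighted graph on n nodes; edge prob p, weights U(0.1, 1)
random_weighted_graph <- function(n, p = 0.6) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) W[i, j] <- W[j, i] <- stats::runif(1, 0.1, 1)
  }
  graph_from_weights(W)
}

# exhaustive shortest-path edge betweenness (unique-path graphs), pair-normalised
brute_edge_betweenness <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  nxt <- matrix(rep(seq_len(n), each = n), n, n)  # next hop on shortest path
  nxt[!is.finite(D)] <- NA
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) {
      D[i, j] <- D[i, k] + D[k, j]
      nxt[i, j] <- nxt[i, k]
    }
  }
  eb <- matrix(0, n, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    a <- s
    while (a != t) {
      b <- nxt[a, t]
      eb[a, b] <- eb[a, b] + 1
      eb[b, a] <- eb[b, a] + 1
      a <- b
    }
  }
  eb / choose(n, 2)
}
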