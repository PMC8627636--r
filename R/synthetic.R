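#' Simulate labelled expression data with planted gene blocks
#'
#' Generates a samples x genes matrix mimicking the shape of small microarray
#' studies: few samples, many genes, a handful of class-relevant genes, and
#' groups of co-expressed genes. Each planted block b shares one latent factor
#' per sample; a block gene is `noise_sd * (sqrt(rho) * latent_b +
#' sqrt(1 - rho) * eps)`, so any two genes of the same block have population
#' correlation `rho`. Genes outside all blocks are independent noise.
#' Relevant genes additionally receive a class-dependent mean shift: samples
#' of the k-th class (0-based) are shifted by `k * delta * noise_sd`.
#' Relevant genes are placed at the head of the blocks, cycling through
#' blocks, so discriminative signal is spread across co-expression clusters.
#' Class labels are balanced to within one sample.
#'
#' Defaults are the scaled-down study conditions used throughout the package
#' tests: 60 samples, 100 genes, 4 equicorrelated blocks of 20 at rho = 0.8,
#' 5 relevant genes with a 2-sd class shift, 2 classes.
#'
#' @param n_samples,n_genes,n_classes dataset dimensions; `n_classes >= 2`.
#' @param n_blocks number of planted co-expression blocks.
#' @param block_sizes integer vector of length `n_blocks`; must sum to at most
#'   `n_genes` (the remainder are free noise genes). The default gives each
#'   block an equal `1/(n_blocks + 1)` share of the genes, leaving the last
#'   share free: blocks of 20 at the default 100 genes and 4 blocks.
#' @param rho within-block correlation in [0, 1).
#' @param n_relevant number of class-relevant genes (`<= n_genes`).
#' @param delta class-mean shift per class index, in units of `noise_sd`.
#' @param noise_sd noise standard deviation (expression units).
#' @param seed integer seed; same seed, identical output.
#' @return list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   data.frame with columns `gene_id`, `block` (integer or NA for free
#'   genes) and `is_relevant`.
#' @export
generate_dataset <- function(n_samples = 60, n_genes = 100, n_classes = 2,
                             n_blocks = 4,
                             block_sizes = rep(max(1L,
                               n_genes %/% (n_blocks + 1L)), n_blocks),
                             rho = 0.8, n_relevant = 5, delta = 2,
                             noise_sd = 1, seed = 1L) {
  stopifnot(n_samples >= 4, n_genes >= 1, n_classes >= 2,
            n_blocks >= 1, length(block_sizes) == n_blocks,
            all(block_sizes >= 1), sum(block_sizes) <= n_genes,
            rho >= 0, rho < 1, n_relevant >= 0, n_relevant <= n_genes,
            delta >= 0, noise_sd > 0)
  set.seed(seed)

  gene_ids <- paste0("G", seq_len(n_genes))
  block_of <- rep(NA_integer_, n_genes)
  pos <- 1L
  for (b in seq_len(n_blocks)) {
    block_of[pos:(pos + block_sizes[b] - 1L)] <- b
    pos <- pos + block_sizes[b]
  }

  # Relevant genes: cycle through blocks taking the next unused slot of each;
  # fall back to free genes if the blocks are exhausted.
  relevant <- integer(0)
  if (n_relevant > 0) {
    block_members <- lapply(seq_len(n_blocks), function(b) which(block_of == b))
    taken <- integer(n_blocks)
    b <- 1L
    while (length(relevant) < n_relevant) {
      tried <- 0L
      while (tried < n_blocks && taken[b] >= length(block_members[[b]])) {
        b <- b %% n_blocks + 1L
        tried <- tried + 1L
      }
      if (tried == n_blocks) break
      taken[b] <- taken[b] + 1L
      relevant <- c(relevant, block_members[[b]][taken[b]])
      b <- b %% n_blocks + 1L
    }
    if (length(relevant) < n_relevant) {
      free <- which(is.na(block_of))
      relevant <- c(relevant, free[seq_len(n_relevant - length(relevant))])
    }
  }

  labels <- rep(paste0("class", seq_len(n_classes)), length.out = n_samples)
  class_idx <- as.integer(factor(labels, levels = unique(labels))) - 1L

  latent <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
  values <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  for (g in seq_len(n_genes)) {
    b <- block_of[g]
    if (!is.na(b))
      values[, g] <- sqrt(rho) * latent[, b] + sqrt(1 - rho) * values[, g]
  }
  values <- values * noise_sd
  if (length(relevant) > 0 && delta > 0)
    values[, relevant] <- values[, relevant] + class_idx * delta * noise_sd

  dataset <- expression_dataset(values, gene_ids, labels)
  truth <- data.frame(
    gene_id = gene_ids,
    block = block_of,
    is_relevant = seq_len(n_genes) %in% relevant,
    stringsAsFactors = FALSE
  )
  list(dataset = dataset, truth = truth)
}
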