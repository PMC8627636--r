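# Small shared helpers.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 2.855 -> 2.86 at two
#' digits), the convention used for all displayed summary tables. Base R's
#' `round()` rounds half to even, which differs on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used to
#' score recovery of planted gene blocks by the clustering step. 1 means
#' identical partitions (up to relabeling), 0 is the expected value for
#' independent partitions.
#'
#' @param a,b vectors of equal length giving cluster labels.
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# Deterministic integer sub-seed derived from a base seed, for staged pipelines.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483629L
}
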