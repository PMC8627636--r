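#' Pareto dominance of fitness vectors
#'
#' `a` dominates `b` iff `a` is no worse in every objective and strictly
#' better in at least one (all objectives minimised). A vector never
#' dominates itself.
#'
#' @param a,b numeric vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop("fitness vectors differ in length (", length(a), " vs ",
         length(b), ")")
  all(a <= b) && any(a < b)
}

#' Crowding distance of archive members
#'
#' NSGA-II style density estimate in objective space: per objective, members
#' are sorted and each interior member accumulates the normalised gap
#' between its neighbours; boundary members (extreme in any objective) get
#' Inf, so objective-wise extremes -- including the lowest classification
#' error found -- are never evicted from a full archive.
#'
#' @param fitness matrix, one row per member, one column per objective.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(fitness) {
  n <- nrow(fitness)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(fitness))) {
    ord <- order(fitness[, j])
    rng <- fitness[ord[n], j] - fitness[ord[1], j]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0)
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
        (fitness[ord[3:n], j] - fitness[ord[1:(n - 2)], j]) / rng
  }
  d
}

#' Initialise a swarm of binary particles
#'
#' Each gene is selected independently with probability equal to its
#' min-max-normalised Fisher score clamped to [0.05, 0.95] (so that every
#' gene keeps a chance of entering or leaving). All-zero masks are redrawn.
#' Velocities start at zero.
#'
#' @param n_particles swarm size (>= 2).
#' @param selection_probs per-gene selection probabilities in [0, 1].
#' @param seed optional integer seed; NULL uses the current RNG state.
#' @return list with `positions` (particles x genes logical matrix) and
#'   `velocities` (numeric matrix of the same shape, all zero).
#' @export
initialize_swarm <- function(n_particles, selection_probs, seed = NULL) {
  stopifnot(n_particles >= 2, length(selection_probs) >= 1,
            all(selection_probs >= 0), all(selection_probs <= 1))
  if (!is.null(seed)) set.seed(seed)
  p <- pmin(0.95, pmax(0.05, selection_probs))
  n_genes <- length(p)
  positions <- matrix(FALSE, n_particles, n_genes)
  for (i in seq_len(n_particles)) {
    repeat {
      mask <- stats::runif(n_genes) < p
      if (any(mask)) break
    }
    positions[i, ] <- mask
  }
  list(positions = positions,
       velocities = matrix(0, n_particles, n_genes))
}

#' One velocity/position update of a binary particle
#'
#' Continuous PSO velocity update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh per-dimension
#' uniforms r1, r2, clamped to `[-v_max, v_max]`, followed by a transfer rule
#' mapping the real velocity to a bit:
#' \describe{
#'   \item{`"vshape"` (default)}{the bit flips with probability `|tanh(v)|`
#'     and is otherwise kept. Positions are stable at zero velocity, so
#'     sparse masks persist once the guides agree a gene is off.}
#'   \item{`"sigmoid"`}{the bit is resampled to 1 with probability
#'     `1 / (1 + exp(-v))`, the classical binary-PSO rule. At zero velocity
#'     every bit is a coin flip, which keeps roughly half the genes selected
#'     and prevents the swarm from holding small subsets; provided for
#'     comparison.}
#' }
#' If the resulting mask is all-zero, the gene with the highest selection
#' probability is re-enabled.
#'
#' @param position logical mask.
#' @param velocity numeric vector, same length.
#' @param pbest,gbest logical masks guiding the update.
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param v_max velocity clamp.
#' @param selection_probs per-gene selection probabilities (all-zero rescue).
#' @param transfer `"vshape"` or `"sigmoid"`.
#' @return list with updated `position` and `velocity`.
#' @export
update_particle <- function(position, velocity, pbest, gbest,
                            w, c1, c2, v_max, selection_probs,
                            transfer = c("vshape", "sigmoid")) {
  transfer <- match.arg(transfer)
  n <- length(position)
  r1 <- stats::runif(n)
  r2 <- stats::runif(n)
  v <- w * velocity + c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  v <- pmin(pmax(v, -v_max), v_max)
  x <- if (transfer == "sigmoid") {
    stats::runif(n) < sigmoid(v)
  } else {
    xor(position, stats::runif(n) < abs(tanh(v)))
  }
  if (!any(x)) x[which.max(selection_probs)] <- TRUE
  list(position = x, velocity = v)
}

#' Cluster-coverage repair of a selection mask
#'
#' Enforces that every gene cluster contributes at least
#' `min(omega, cluster size)` selected genes. Deficient clusters are
#' processed in ascending index; each missing slot is filled with the
#' cluster's highest-Fisher unselected gene, swapped one-for-one against the
#' globally lowest-Fisher selected gene whose removal does not make its own
#' cluster deficient. When no such donor exists the gene is added without
#' removal and the subset grows. `omega = 0` leaves the mask untouched.
#' Deterministic given its inputs.
#'
#' @param mask logical selection mask over the clustered genes.
#' @param membership integer cluster index per gene (1..k).
#' @param fisher numeric Fisher scores per gene.
#' @param omega required per-cluster coverage (non-negative integer).
#' @return the repaired logical mask.
#' @export
repair <- function(mask, membership, fisher, omega) {
  stopifnot(length(mask) == length(membership),
            length(mask) == length(fisher), omega >= 0)
  if (omega == 0) return(mask)
  k <- max(membership)
  cluster_sizes <- tabulate(membership, k)
  sel_count <- tabulate(membership[mask], k)
  need <- pmin(omega, cluster_sizes) - sel_count
  for (cl in which(need > 0)) {
    for (slot in seq_len(need[cl])) {
      cand <- which(membership == cl & !mask)
      if (length(cand) == 0) break
      add <- cand[order(-fisher[cand], cand)][1]
      sel <- which(mask)
      donor_ok <- membership[sel] != cl &
        (sel_count[membership[sel]] - 1L) >=
          pmin(omega, cluster_sizes[membership[sel]])
      donors <- sel[donor_ok]
      if (length(donors) > 0) {
        donor <- donors[order(fisher[donors], donors)][1]
        mask[donor] <- FALSE
        sel_count[membership[donor]] <- sel_count[membership[donor]] - 1L
      }
      mask[add] <- TRUE
      sel_count[cl] <- sel_count[cl] + 1L
    }
  }
  mask
}

#' Insert a candidate into a bounded Pareto archive
#'
#' The candidate enters iff no member dominates it; members it dominates are
#' removed (a candidate whose mask is already present is ignored). If the
#' archive then exceeds its capacity, the member with the smallest crowding
#' distance is evicted, preserving objective-wise extremes.
#'
#' @param archive list of members, each a list with `mask` (logical) and
#'   `fitness` (numeric vector).
#' @param mask,fitness the candidate.
#' @param capacity maximum archive size.
#' @return the updated archive (a list).
#' @export
update_archive <- function(archive, mask, fitness, capacity) {
  if (length(archive) > 0) {
    for (m in archive) {
      if (dominates(m$fitness, fitness)) return(archive)
      if (identical(m$mask, mask)) return(archive)
    }
    dominated <- vapply(archive, function(m) dominates(fitness, m$fitness),
                        logical(1))
    archive <- archive[!dominated]
  }
  archive <- c(archive, list(list(mask = mask, fitness = fitness)))
  if (length(archive) > capacity) {
    fmat <- do.call(rbind, lapply(archive, `[[`, "fitness"))
    archive <- archive[-which.min(crowding_distance(fmat))]
  }
  archive
}

#' Draw a global guide from the archive
#'
#' Binary tournament on crowding distance: two members are drawn uniformly
#' (with replacement) and the less crowded one wins, biasing guidance
#' towards under-explored regions of the Pareto front. Uses the current RNG
#' state.
#'
#' @param archive non-empty archive list.
#' @return the winning member's logical mask.
#' @export
select_gbest <- function(archive) {
  if (length(archive) == 0) stop("empty archive")
  if (length(archive) == 1) return(archive[[1]]$mask)
  fmat <- do.call(rbind, lapply(archive, `[[`, "fitness"))
  cd <- crowding_distance(fmat)
  pick <- sample.int(length(archive), 2, replace = TRUE)
  winner <- if (cd[pick[2]] > cd[pick[1]]) pick[2] else pick[1]
  archive[[winner]]$mask
}

#' Final solution from a Pareto archive
#'
#' Among the mutually nondominated members, picks the one with the lowest
#' classification error (f1); ties are broken by smaller subset size (f5),
#' then by lower reciprocal specificity (f4), then by the lexicographically
#' smallest sequence of selected gene indices.
#'
#' @param archive non-empty archive list.
#' @return the chosen member (list with `mask` and `fitness`).
#' @export
final_solution <- function(archive) {
  if (length(archive) == 0) stop("empty archive")
  fmat <- do.call(rbind, lapply(archive, `[[`, "fitness"))
  # selected positions encoded as "0" so earlier selections sort lower
  keys <- vapply(archive, function(m)
    paste(1L - as.integer(m$mask), collapse = ""), character(1))
  ord <- order(fmat[, 1], fmat[, 5], fmat[, 4], keys)
  archive[[ord[1]]]
}
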