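test_that("Pareto dominance needs no-worse everywhere plus one strict win", {
  a <- c(1, 2, 3, 4, 5)
  expect_false(dominates(a, a))                       # irreflexive
  expect_true(dominates(a, a + 1))
  expect_true(dominates(a, c(1, 2, 3, 4, 6)))
  expect_false(dominates(c(1, 2, 3, 4, 6), a))
  expect_false(dominates(c(0, 9, 0, 0, 0), c(1, 1, 1, 1, 1)))
  expect_error(dominates(1:4, 1:5), "differ in length")
})

test_that("dominance is antisymmetric and transitive on random vectors", {
  set.seed(42)
  v <- matrix(sample(0:3, 5 * 60, replace = TRUE), ncol = 5)  # ties likely
  for (rep in 1:300) {
    i <- sample(60, 3)
    a <- v[i[1], ]; b <- v[i[2], ]; cc <- v[i[3], ]
    expect_false(dominates(a, b) && dominates(b, a))
    if (dominates(a, b) && dominates(b, cc)) expect_true(dominates(a, cc))
  }
})

test_that("swarm initialisation is seeded, Fisher-guided and never empty", {
  probs <- c(0.9, 0.5, 0.05, 0.05, 0.05)
  s1 <- initialize_swarm(20, probs, seed = 8)
  s2 <- initialize_swarm(20, probs, seed = 8)
  expect_identical(s1$positions, s2$positions)
  expect_true(all(rowSums(s1$positions) >= 1))
  expect_equal(s1$velocities, matrix(0, 20, 5))
  # with uniform probability 0.5 the mean density is near 0.5
  su <- initialize_swarm(1000, rep(0.5, 50), seed = 1)
  expect_equal(mean(su$positions), 0.5, tolerance = 0.1)
})

test_that("velocity update follows the inertia-cognitive-social form and clamps", {
  # replay the RNG: with w = 0.5, v = 1, c1 = c2 = 2, (pbest-x) = 1,
  # (gbest-x) = 0, the new velocity is 0.5 + 2*r1
  set.seed(5)
  r1 <- runif(1); runif(1); runif(1)       # r1, r2, transfer draw
  set.seed(5)
  upd <- update_particle(position = FALSE, velocity = 1,
                         pbest = TRUE, gbest = FALSE,
                         w = 0.5, c1 = 2, c2 = 2, v_max = 10,
                         selection_probs = 1)
  expect_equal(upd$velocity, 0.5 * 1 + 2 * r1 * 1)
  # the fixed-draw arithmetic of the update: r1 = r2 = 0.5 gives 1.5
  expect_equal(0.5 * 1 + 2 * 0.5 * 1 + 2 * 0.5 * 0, 1.5)
  # clamping property
  set.seed(6)
  for (rep in 1:20) {
    u <- update_particle(rep(FALSE, 10), rep(10, 10), rep(TRUE, 10),
                         rep(TRUE, 10), 0.9, 2, 2, 4, runif(10))
    expect_true(all(abs(u$velocity) <= 4))
  }
})

test_that("V-shaped transfer keeps positions at zero velocity", {
  set.seed(7)
  x <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  u <- update_particle(x, rep(0, 5), x, x, 0.7, 2, 2, 4, rep(0.5, 5),
                       transfer = "vshape")
  expect_identical(u$position, x)          # no flips: |tanh(0)| = 0
})

test_that("sigmoid transfer resamples bits at one half for zero velocity", {
  set.seed(8)
  x <- rep(TRUE, 10000)
  u <- update_particle(x, rep(0, 10000), x, x, 0.7, 2, 2, 4, rep(0.5, 10000),
                       transfer = "sigmoid")
  expect_equal(mean(u$position), 0.5, tolerance = 0.02)
})

test_that("repair reproduces the worked ten-gene example", {
  membership <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 2)
  fisher <- c(0.9, 0.1, 0.8, 0.2, 0.3, 0.4, 0.05, 0.5, 0.7, 0.6)
  mask <- seq_len(10) %in% c(1, 3, 7, 10)       # cluster 3 uncovered
  out <- repair(mask, membership, fisher, omega = 1)
  expect_equal(which(out), c(1, 3, 9, 10))      # G7 out, G9 in
  # already covered: unchanged; omega 0: always unchanged
  expect_identical(repair(out, membership, fisher, 1), out)
  expect_identical(repair(mask, membership, fisher, 0), mask)
})

test_that("repair covers every cluster and preserves size when donors exist", {
  set.seed(12)
  for (rep in 1:30) {
    n <- 30
    membership <- sample(1:5, n, replace = TRUE)
    fisher <- runif(n)
    mask <- runif(n) < 0.4
    if (!any(mask)) mask[1] <- TRUE
    out <- repair(mask, membership, fisher, omega = 1)
    cover <- tabulate(membership[out], 5)
    sizes <- tabulate(membership, 5)
    expect_true(all(cover >= pmin(1, sizes)))
    # coverage never decreases
    expect_true(all(cover >= pmin(1, tabulate(membership[mask], 5))))
    # size preserved when enough donors existed, never shrinks otherwise
    expect_gte(sum(out), sum(mask))
    if (sum(mask) >= 5) expect_lte(sum(out), max(sum(mask), 5))
  }
})

test_that("archive stays nondominated, bounded and evicts the most crowded-in", {
  arch <- list()
  arch <- update_archive(arch, c(TRUE, FALSE), c(1, 1, 1, 1, 1), 10)
  # dominated candidate rejected
  arch2 <- update_archive(arch, c(FALSE, TRUE), c(2, 2, 2, 2, 2), 10)
  expect_length(arch2, 1)
  # candidate dominating two members replaces both
  arch3 <- list(list(mask = c(TRUE, FALSE), fitness = c(3, 3, 3, 3, 3)),
                list(mask = c(FALSE, TRUE), fitness = c(4, 4, 4, 4, 4)))
  arch3 <- update_archive(arch3, c(TRUE, TRUE), c(2, 2, 2, 2, 2), 10)
  expect_length(arch3, 1)
  expect_equal(arch3[[1]]$fitness, c(2, 2, 2, 2, 2))

  # capacity eviction removes a member with minimal crowding distance
  set.seed(33)
  arch4 <- list()
  masks <- lapply(1:12, function(i) seq_len(12) == i)
  # nondominated set: decreasing f1, increasing f5
  for (i in 1:12)
    arch4 <- update_archive(arch4, masks[[i]], c(12 - i, 1, 1, 1, i), 8)
  expect_lte(length(arch4), 8)
  fmat <- do.call(rbind, lapply(arch4, `[[`, "fitness"))
  for (i in seq_along(arch4)) for (j in seq_along(arch4)) {
    if (i != j) expect_false(dominates(fmat[i, ], fmat[j, ]))
  }
  # objective-wise extremes survive eviction (infinite crowding)
  expect_equal(min(fmat[, 1]), 0)
  expect_equal(min(fmat[, 5]), 1)
})

test_that("gbest tournament prefers less crowded members, reproducibly", {
  arch <- list(list(mask = c(TRUE, FALSE), fitness = c(1, 1, 1, 1, 1)))
  expect_equal(select_gbest(arch), c(TRUE, FALSE))
  set.seed(14)
  a <- replicate(5, select_gbest(list(
    list(mask = c(TRUE, FALSE), fitness = c(0, 2, 1, 1, 1)),
    list(mask = c(FALSE, TRUE), fitness = c(2, 0, 1, 1, 1)))))
  set.seed(14)
  b <- replicate(5, select_gbest(list(
    list(mask = c(TRUE, FALSE), fitness = c(0, 2, 1, 1, 1)),
    list(mask = c(FALSE, TRUE), fitness = c(2, 0, 1, 1, 1)))))
  expect_identical(a, b)
})

test_that("final solution minimises error, then size, then 1/specificity", {
  arch <- list(
    list(mask = c(TRUE, TRUE, TRUE), fitness = c(0.1, 1, 1, 1, 8)),
    list(mask = c(TRUE, TRUE, FALSE), fitness = c(0.1, 2, 2, 1, 5)),
    list(mask = c(TRUE, FALSE, FALSE), fitness = c(0.2, 0, 3, 1, 2)))
  best <- final_solution(arch)
  expect_equal(best$fitness[5], 5)
  # the returned member belongs to the archive
  expect_true(any(vapply(arch, function(m) identical(m, best), logical(1))))
  expect_error(final_solution(list()), "empty archive")
})
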