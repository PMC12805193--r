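test_that("penalty adjustment forbids exactly the sub-threshold pairs", {
  A <- adjust_dissimilarities(d4, 3)
  expect_equal(A[1, 2], -22)  # penalty = sum of pairs (21) + 1
  expect_equal(A[1, 3], -22)
  expect_equal(A[1, 4], 3)
  expect_equal(A[2, 3], 4)
  expect_identical(attr(A, "flavor"), "adjusted")
  expect_equal(adjust_dissimilarities(d4, 0)[upper.tri(d4)],
               d4[upper.tri(d4)])
  Aall <- adjust_dissimilarities(d4, 7)
  expect_true(all(Aall[upper.tri(Aall)] == -22))
})

test_that("exact maximum diversity matches enumeration", {
  part <- optimal_diversity(d4, c(2, 2))
  expect_equal(diversity(d4, part), 7)
  adj <- adjust_dissimilarities(d4, 3)
  part2 <- optimal_diversity(adj, c(2, 2))
  expect_equal(canonical_clusters(part2), c(1, 2, 2, 1))
  expect_equal(diversity(d4, part2), 7)
  expect_equal(diversity(matrix(c(0, 5, 5, 0), 2),
                         optimal_diversity(matrix(c(0, 5, 5, 0), 2), c(1, 1))),
               0)
  set.seed(12)
  for (i in 1:15) {
    inst <- random_instance(8, 2)
    ex <- exhaustive_search(inst$D, inst$sizes)
    expect_equal(diversity(inst$D, optimal_diversity(inst$D, inst$sizes)),
                 ex$max_diversity, tolerance = 1e-9)
  }
})

test_that("the constraint method attains maximum diversity at optimal dispersion", {
  e <- optimal_bicriterion(d4, 2, c(2, 2))
  expect_equal(e$diversity, 7)
  expect_equal(e$dispersion, 3)
  expect_equal(e$partition, c(1, 2, 2, 1))
  # degenerate: all distances equal
  Deq <- matrix(2, 4, 4); diag(Deq) <- 0
  eq <- optimal_bicriterion(Deq, 2, c(2, 2))
  expect_equal(eq$diversity, 2 * 2)  # two within pairs at distance 2
  expect_equal(eq$dispersion, 2)
  set.seed(14)
  for (i in 1:15) {
    inst <- random_instance(8, 2)
    ex <- exhaustive_search(inst$D, inst$sizes)
    e <- optimal_bicriterion(inst$D, inst$K, inst$sizes)
    expect_equal(e$dispersion, ex$max_dispersion)
    expect_equal(e$diversity, ex$best_diversity_at_max_dispersion,
                 tolerance = 1e-9)
  }
})

test_that("the threshold sweep recovers the exact Pareto frontier", {
  S <- exact_pareto_set(d4, 2, c(2, 2))
  expect_equal(length(S), 1L)
  expect_equal(S$entries[[1]]$diversity, 7)
  expect_equal(S$entries[[1]]$dispersion, 3)
  set.seed(15)
  for (i in 1:10) {
    inst <- random_instance(8, 2)
    f1 <- as.data.frame(exact_pareto_set(inst$D, inst$K, inst$sizes))
    f2 <- as.data.frame(exhaustive_search(inst$D, inst$sizes)$pareto)
    f1 <- f1[order(f1$dispersion), ]
    f2 <- f2[order(f2$dispersion), ]
    expect_equal(nrow(f1), nrow(f2))
    expect_equal(as.matrix(f1), as.matrix(f2), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("penalty soundness: adjusted optima avoid forbidden pairs when possible", {
  set.seed(16)
  for (i in 1:15) {
    inst <- random_instance(draw_divisible(6:10, 2), 2)
    thr <- sample(sort(inst$D[upper.tri(inst$D)]), 1)
    sep <- tryCatch(
      satisfy_cannot_link(which(upper.tri(inst$D) & inst$D < thr,
                                arr.ind = TRUE),
                          nrow(inst$D), inst$K, inst$sizes),
      antipart_infeasible = function(e) NULL)
    part <- optimal_diversity(adjust_dissimilarities(inst$D, thr), inst$sizes)
    has_forbidden <- dispersion(inst$D, part) < thr
    if (!is.null(sep)) expect_false(has_forbidden)
    # reported scores are never contaminated by the penalty
    expect_true(diversity(inst$D, part) >= 0)
  }
})
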