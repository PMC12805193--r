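test_that("synthetic datasets match the declared generative process", {
  set.seed(71)
  X <- generate_dataset(10, 3)
  expect_equal(dim(X), c(10L, 3L))
  set.seed(72); A <- generate_dataset(20, 2, sd = 2)
  set.seed(72); B <- generate_dataset(20, 2, sd = 2)
  expect_identical(A, B)
  set.seed(73)
  big <- generate_dataset(10000, 2, sd = 2)
  # CLT bands: mean within 5 SE of 0, sd within 5 SE of 2
  expect_lt(abs(mean(big[, 1])), 5 * 2 / sqrt(10000))
  expect_lt(abs(sd(big[, 1]) - 2), 5 * 2 / sqrt(2 * 10000))
  expect_lt(abs(cor(big[, 1], big[, 2])), 5 / sqrt(10000))
})

test_that("the good-solution rule applies a scale-invariant 0.1% band", {
  expect_equal(good_solution_flags(c(100, 99.95, 99.8)),
               c(TRUE, TRUE, FALSE))
  expect_true(good_solution_flags(42))
  expect_equal(good_solution_flags(c(5, 5, 5)), rep(TRUE, 3))
  set.seed(74)
  d <- runif(6, 90, 100)
  expect_equal(good_solution_flags(d), good_solution_flags(d * 1e6))
})

test_that("restriction labels count canonical duplicates", {
  distinct <- t(vapply(1:20, function(i) sample(rep(1:2, each = 3)),
                       integer(6)))
  distinct <- unique(t(apply(distinct, 1L, canonical_clusters)))
  expect_equal(label_restriction(distinct)$label, "none")
  same <- matrix(rep(c(1, 1, 2, 2), each = 15), 15, 4, byrow = FALSE)
  same <- matrix(c(1, 1, 2, 2), 15, 4, byrow = TRUE)
  expect_equal(label_restriction(same)$label, "maximum")
  mix <- rbind(distinct, distinct[1, ])
  lab <- label_restriction(mix)
  expect_equal(lab$label, "some")
  expect_equal(lab$duplicate_count, 1L)
  # invariant to cluster relabeling of the initializations
  relab <- rbind(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(label_restriction(relab)$label, "maximum")
})

test_that("the benchmark harness scores every method at optimal dispersion", {
  res <- run_benchmark(benchmark_config(reps_per_K = 2, K_set = 2:3,
                                        restarts = 10, seed = 75))
  expect_equal(nrow(res), 2 * 2 * 6)
  expect_true(all(res$dispersion == res$optimal_dispersion))
  expect_true(all(res$restriction %in% c("none", "some", "maximum")))
  expect_true(is.logical(res$good))
  # per dataset at least one method is flagged good (the best one)
  per <- tapply(res$good, res$dataset, any)
  expect_true(all(per))
  agg <- summarize_benchmark(res)
  expect_true(all(agg$prop_good >= 0 & agg$prop_good <= 1))
  agg_k <- summarize_benchmark(res, by = "K")
  expect_equal(nrow(agg_k), 2 * 6)
})

test_that("exhaustive enumeration matches the closed-form counts", {
  ex <- exhaustive_search(d4, c(2, 2))
  expect_equal(ex$n_partitions, 3L)
  expect_equal(ex$max_diversity, 7)
  expect_equal(ex$max_dispersion, 3)
  expect_equal(length(ex$pareto), 1L)
  expect_equal(nrow(enumerate_partitions(c(2, 2, 2))), 15L)
  expect_equal(nrow(enumerate_partitions(c(5, 5))),
               as.numeric(partition_count(10, 2)))
  tiny <- matrix(c(0, 4, 4, 0), 2)
  ex2 <- exhaustive_search(tiny, c(2))
  expect_equal(ex2$max_diversity, 4)
  expect_equal(ex2$max_dispersion, 4)
  expect_error(exhaustive_search(distance_matrix(matrix(rnorm(40), 20)),
                                 rep(10, 2), limit = 100), "too large")
})
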