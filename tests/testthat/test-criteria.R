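test_that("distance construction matches closed forms", {
  expect_equal(distance_matrix(matrix(c(0, 2), 2, 1))[1, 2], 4)
  expect_equal(distance_matrix(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))[1, 2], 25)
  expect_equal(distance_matrix(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE),
                               "euclidean")[1, 2], 5)
  expect_equal(distance_matrix(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE),
                               "manhattan")[1, 2], 7)
  expect_equal(distance_matrix(matrix(c(1, 1), 2, 1))[1, 2], 0)
  expect_error(distance_matrix(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("normalized Levenshtein distances are a bounded metric-like measure", {
  expect_equal(levenshtein_matrix(c("abc", "abc"))[1, 2], 0)
  expect_equal(levenshtein_matrix(c("a", "b"))[1, 2], 2 / 3)
  expect_equal(levenshtein_matrix(c("ab", "a"))[1, 2], 0.5)
  expect_error(levenshtein_matrix(c("", "a")), "nonempty")
  words <- c("kettle", "kitten", "mitten", "sitting", "sofa")
  L <- levenshtein_matrix(words)
  expect_true(all(L >= 0 & L <= 1))
  expect_equal(L, t(L))
  expect_true(all(diag(L) == 0))
})

test_that("k-plus augmentation appends squared deviations", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  A <- kplus_augment(X)
  expect_equal(ncol(A), 4L)
  expect_equal(unname(A[, 3]), c(1, 0, 1))  # mean 2, squared deviations
  expect_equal(unname(A[, 4]), c(0, 0, 0))  # constant feature
  expect_error(kplus_augment(X, moments = 3), "moments")
})

test_that("diversity and dispersion on the toy instance match enumeration", {
  expect_equal(diversity(d4, c(1, 1, 2, 2)), 7)
  expect_equal(diversity(d4, 1:4), 0)
  expect_equal(diversity(d4, rep(1, 4)), 21)
  expect_equal(average_diversity(d4, c(1, 1, 2, 2)), 3.5)
  expect_equal(average_diversity(d4, c(1, 1, 2, 2)),
               diversity(d4, c(1, 1, 2, 2)) / 2)
  expect_equal(average_diversity(d4, 1:4), 0)
  expect_equal(dispersion(d4, c(1, 1, 2, 2)), 1)
  expect_equal(dispersion(d4, c(1, 2, 2, 1)), 3)
  expect_identical(dispersion(d4, 1:4), Inf)
  expect_error(diversity(d4, c(1, 1, 2)), "length")
})

test_that("k-means criterion equals its centroid form and singleton limit", {
  X <- matrix(c(0, 2, 4, 6), 4, 1)
  expect_equal(kmeans_criterion(X, c(1, 1, 2, 2)), 4)  # centroids 1 and 5
  expect_equal(kmeans_criterion(X, 1:4), 0)
  expect_equal(kmeans_criterion(X, c(1, 1, 2, 2)),
               average_diversity(distance_matrix(X), c(1, 1, 2, 2)))
})

test_that("criterion identities hold on random inputs", {
  set.seed(31)
  for (i in 1:20) {
    n <- draw_divisible(seq(4, 12), 2)
    K <- sample(2:3, 1)
    if (n %% K != 0) K <- 2
    X <- matrix(rnorm(n * 3, sd = sample(1:3, 1)), n)
    D <- distance_matrix(X)
    cl <- random_partition(rep(n %/% K, K))
    tot <- sum(D[upper.tri(D)])
    within <- diversity(D, cl)
    across <- sum(vapply(seq_len(n - 1), function(i) {
      sum(D[i, (i + 1):n][cl[(i + 1):n] != cl[i]])
    }, numeric(1)))
    # conservation: within + across = total pairwise sum
    expect_equal(within + across, tot, tolerance = 1e-9)
    # k-means criterion == average diversity on squared Euclidean distances
    expect_equal(kmeans_criterion(X, cl), average_diversity(D, cl),
                 tolerance = 1e-9)
    # within-cluster SS + weighted between-centroid SS is partition-free
    cents <- do.call(rbind, lapply(split(seq_len(n), cl),
                                   function(ix) colMeans(X[ix, , drop = FALSE])))
    gc <- colMeans(X)
    between <- sum(tabulate(cl) * rowSums(sweep(cents, 2, gc)^2))
    expect_equal(kmeans_criterion(X, cl) + between,
                 sum(sweep(X, 2, gc)^2), tolerance = 1e-9)
    # equal sizes: average diversity is diversity / group size
    expect_equal(average_diversity(D, cl), diversity(D, cl) / (n / K))
  }
})

test_that("partition counts are exact and agree with enumeration", {
  expect_identical(partition_count(4, 2), "3")
  expect_identical(partition_count(30, 3), "925166131890")
  expect_identical(partition_count(8, 1), "1")
  expect_error(partition_count(7, 2), "divisor")
  for (N in c(4, 6, 8, 9, 10)) {
    for (K in 2:3) {
      if (N %% K != 0) next
      n_enum <- nrow(enumerate_partitions(rep(N %/% K, K)))
      expect_identical(partition_count(N, K), as.character(n_enum))
    }
  }
  # a count far beyond double precision: digit length checked against the
  # log-gamma evaluation of the same formula
  expect_equal(nchar(partition_count(120, 4)),
               floor((lgamma(121) - 4 * lgamma(31) - lgamma(5)) /
                       log(10)) + 1)
})
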