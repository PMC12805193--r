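test_that("cannot-link graphs collect all pairs at or below the threshold", {
  expect_equal(cannot_link_graph(d4, 1)$edges, cbind(1L, 2L))
  g2 <- cannot_link_graph(d4, 2)
  expect_equal(g2$edges[order(g2$edges[, 2]), ], cbind(1L, 2:3))
  expect_equal(nrow(cannot_link_graph(d4, 0.5)$edges), 0L)
})

test_that("bounded coloring separates feasibility from infeasibility", {
  g2 <- cannot_link_graph(d4, 2)
  res <- k_color_with_cardinalities(g2, 2, c(2, 2))
  expect_true(res$feasible)
  col <- res$coloring
  expect_true(col[1] != col[2] && col[1] != col[3])
  # theta = 3: vertex 1 conflicts with 2,3,4 -> cardinalities make it
  # infeasible although the graph itself is 2-colorable
  g3 <- cannot_link_graph(d4, 3)
  expect_false(k_color_with_cardinalities(g3, 2, c(2, 2))$feasible)
  expect_true(k_color_with_cardinalities(g3, 2)$feasible)
  empty <- cannot_link_graph(d4, 0.5)
  expect_true(k_color_with_cardinalities(empty, 2, c(2, 2))$feasible)
})

test_that("the threshold sweep certifies the exact optimum on the toy instance", {
  opt <- optimal_dispersion(d4, 2, c(2, 2))
  expect_equal(opt$dispersion, 3)
  expect_equal(opt$theta_star, 2)
  free <- optimal_dispersion(d4, 2)
  expect_equal(free$dispersion, 4)  # {1},{2,3,4}
  tiny <- optimal_dispersion(matrix(c(0, 1, 1, 0), 2), 2, c(1, 1))
  expect_identical(tiny$dispersion, Inf)
})

test_that("completions respect capacities and never change the dispersion", {
  set.seed(21)
  opt <- optimal_dispersion(d4, 2, c(2, 2))
  full <- complete_partition(opt)
  expect_equal(canonical_clusters(full), c(1, 2, 2, 1))  # forced completion
  expect_equal(dispersion(d4, full), opt$dispersion)
  for (i in 1:25) {
    inst <- random_instance(draw_divisible(seq(8, 24), 2), sample(2:3, 1))
    if (inst$sizes[1] * inst$K != nrow(inst$D)) next
    opt <- optimal_dispersion(inst$D, inst$K, inst$sizes)
    for (r in 1:4) {
      cp <- complete_partition(opt)
      expect_equal(tabulate(cp, nbins = inst$K), inst$sizes)
      expect_equal(dispersion(inst$D, cp), opt$dispersion)
    }
  }
  # fully assigned certificates are returned unchanged
  opt2 <- optimal_dispersion(d4, 2, c(2, 2))
  opt2$partial <- c(1L, 2L, 2L, 1L)
  expect_equal(complete_partition(opt2), c(1L, 2L, 2L, 1L))
})

test_that("the sweep is invariant to object relabeling (tied pairs included)", {
  set.seed(33)
  D <- distance_matrix(matrix(round(rnorm(36), 1), 12))  # rounding forces ties
  ref <- optimal_dispersion(D, 3, rep(4, 3))$dispersion
  for (r in 1:5) {
    perm <- sample(12)
    expect_equal(optimal_dispersion(D[perm, perm], 3, rep(4, 3))$dispersion,
                 ref)
  }
})

test_that("general cannot-link constraints are satisfied or reported infeasible", {
  set.seed(4)
  p <- satisfy_cannot_link(cbind(1, 2), 4, 2, c(2, 2))
  expect_true(p[1] != p[2])
  expect_equal(sort(tabulate(p)), c(2, 2))
  expect_error(satisfy_cannot_link(rbind(c(1, 2), c(1, 3), c(1, 4)),
                                   4, 2, c(2, 2)),
               class = "antipart_infeasible")
  p0 <- satisfy_cannot_link(matrix(integer(0), 0, 2), 6, 3, c(2, 2, 2))
  expect_equal(sort(tabulate(p0)), c(2, 2, 2))
  # separated pairs stay separated on random instances
  for (i in 1:10) {
    pairs <- t(utils::combn(8, 2))[sample(28, 5), ]
    res <- tryCatch(satisfy_cannot_link(pairs, 8, 2, c(4, 4)),
                    antipart_infeasible = function(e) NULL)
    if (!is.null(res))
      expect_true(all(res[pairs[, 1]] != res[pairs[, 2]]))
  }
})
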