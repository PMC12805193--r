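test_that("weighted bicriterion score hits the pure criteria at the ends", {
  expect_equal(weighted_bicriterion(7, 3, 1), 7)
  expect_equal(weighted_bicriterion(7, 3, 0), 3)
  expect_equal(weighted_bicriterion(7, 3, 0.5), 5)
  expect_equal(weighted_bicriterion(7, Inf, 1), 7)  # sentinel never leaks
  expect_error(weighted_bicriterion(1, 1, 2), "w")
})

test_that("local search reaches 2-swap optima and never worsens the objective", {
  expect_equal(diversity(d4, lcw(d4, c(1, 1, 2, 2))), 7)
  set.seed(41)
  for (i in 1:10) {
    inst <- random_instance(10, 2)
    init <- random_partition(inst$sizes)
    out <- lcw(inst$D, init)
    expect_gte(diversity(inst$D, out), diversity(inst$D, init))
    expect_equal(tabulate(out), inst$sizes)
    # exhaustive neighborhood scan: no single pairwise swap improves
    best <- diversity(inst$D, out)
    for (i1 in 1:9) for (j1 in (i1 + 1):10) {
      if (out[i1] == out[j1]) next
      sw <- out; sw[c(i1, j1)] <- sw[c(j1, i1)]
      expect_lte(diversity(inst$D, sw), best + 1e-9)
    }
    # a local optimum is a fixed point (up to canonical relabeling)
    expect_equal(lcw(inst$D, out), canonical_clusters(out))
  }
})

test_that("restricted local search always preserves the optimal dispersion", {
  e <- restricted_lcw(d4, d4, K = 2, sizes = c(2, 2))
  expect_equal(e$diversity, 7)
  expect_equal(e$dispersion, 3)
  set.seed(43)
  for (i in 1:20) {
    inst <- random_instance(draw_divisible(seq(10, 30), 2), sample(2:3, 1))
    if (inst$sizes[1] * inst$K != nrow(inst$D)) next
    opt <- optimal_dispersion(inst$D, inst$K, inst$sizes)
    e <- restricted_lcw(inst$D, inst$D, K = inst$K, sizes = inst$sizes,
                        opt = opt)
    expect_equal(e$dispersion, opt$dispersion)
    expect_equal(e$diversity, diversity(inst$D, e$partition))
  }
})

test_that("bicriterion interchange records non-dominated realized exchanges", {
  res <- bpi(d4, d4, w = 0.5, init = c(1, 1, 2, 2))
  sel <- select_entry(res$pareto, "max-dispersion")
  expect_equal(sel$diversity, 7)
  expect_equal(sel$dispersion, 3)
  # w = 1 reduces to the diversity-only search of lcw
  set.seed(44)
  for (i in 1:5) {
    inst <- random_instance(12, 2)
    init <- random_partition(inst$sizes)
    expect_equal(bpi(inst$D, inst$D, w = 1, init = init)$partition,
                 lcw(inst$D, init))
  }
  # Pareto set stays mutually non-dominated through chained calls
  S <- pareto_set()
  for (i in 1:5) {
    S <- bpi(d4, d4, w = runif(1), init = random_partition(c(2, 2)), S = S)$pareto
    for (a in seq_along(S$entries)) for (b in seq_along(S$entries))
      if (a != b) expect_false(dominates(S$entries[[a]], S$entries[[b]]))
  }
})

test_that("the pair-swap perturbation matches an R mirror on one RNG stream", {
  mirror <- function(cl, p) {
    n <- length(cl)
    events <- 0L; eligible <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (cl[i] != cl[j]) {
        eligible <- eligible + 1L
        if (runif(1) < p) { cl[c(i, j)] <- cl[c(j, i)]; events <- events + 1L }
      }
    }
    list(cl = cl, events = events, eligible = eligible)
  }
  cl0 <- rep(1:2, each = 30)
  set.seed(51); out_c <- ils_perturb(cl0, 0.07)
  set.seed(51); out_r <- mirror(cl0, 0.07)
  expect_identical(out_c, as.integer(out_r$cl))
  expect_equal(tabulate(out_c), tabulate(cl0))
  # swap events are i.i.d. bernoulli(p) over eligible inspections
  set.seed(52)
  tot <- c(events = 0, eligible = 0)
  for (r in 1:300) {
    m <- mirror(cl0, 0.05)
    tot <- tot + c(m$events, m$eligible)
  }
  phat <- tot[["events"]] / tot[["eligible"]]
  se <- sqrt(0.05 * 0.95 / tot[["eligible"]])
  expect_lt(abs(phat - 0.05), 3 * se)
  # sizes preserved under many random partitions and probabilities
  set.seed(53)
  for (r in 1:200) {
    sizes <- c(3, 4, 5)
    cl <- random_partition(sizes)
    expect_equal(tabulate(ils_perturb(cl, runif(1, 0.01, 0.99))), sizes)
  }
})

test_that("bils is reproducible and its hybrid modes certify optimal dispersion", {
  set.seed(61)
  S1 <- bils(d4, d4, K = 2, config = bils_config(10, init = "hybrid-all"))
  set.seed(61)
  S2 <- bils(d4, d4, K = 2, config = bils_config(10, init = "hybrid-all"))
  expect_identical(lapply(S1$entries, `[[`, "partition"),
                   lapply(S2$entries, `[[`, "partition"))
  expect_equal(length(S1), 1L)
  expect_equal(S1$entries[[1]]$diversity, 7)
  expect_equal(S1$entries[[1]]$dispersion, 3)
  for (mode in c("vanilla", "hybrid-1", "hybrid-all")) {
    Sm <- bils(d4, d4, K = 2, config = bils_config(10, init = mode))
    expect_equal(select_entry(Sm, "max-dispersion")$dispersion, 3)
  }
  set.seed(62)
  for (i in 1:12) {
    inst <- random_instance(draw_divisible(seq(10, 24), 2), sample(2:3, 1))
    if (inst$sizes[1] * inst$K != nrow(inst$D)) next
    opt <- optimal_dispersion(inst$D, inst$K, inst$sizes)
    for (mode in c("hybrid-1", "hybrid-all")) {
      S <- bils(inst$D, inst$D, inst$K, inst$sizes,
                bils_config(8, 4, init = mode), opt = opt)
      sel <- select_entry(S, "max-dispersion")
      expect_equal(sel$dispersion, opt$dispersion)
      for (e in S$entries)
        expect_equal(tabulate(e$partition, nbins = inst$K), inst$sizes)
    }
  }
})

test_that("with equal sizes the size-normalized criterion tracks the plain one", {
  set.seed(63)
  for (i in 1:8) {
    inst <- random_instance(12, 3)
    init <- random_partition(inst$sizes)
    expect_equal(lcw(inst$D, init, "diversity"),
                 lcw(inst$D, init, "average-diversity"))
  }
})

test_that("small-instance bils recovers the exhaustive Pareto frontier", {
  set.seed(64)
  hits <- 0L; trials <- 30L
  for (i in seq_len(trials)) {
    inst <- random_instance(draw_divisible(c(6, 8, 10), 2), 2)
    ex <- exhaustive_search(inst$D, inst$sizes)
    S <- bils(inst$D, inst$D, inst$K, inst$sizes, bils_config(50))
    f1 <- as.data.frame(S); f2 <- as.data.frame(ex$pareto)
    f1 <- f1[order(f1$diversity, f1$dispersion), ]
    f2 <- f2[order(f2$diversity, f2$dispersion), ]
    # every returned entry lies on the true frontier
    for (r in seq_len(nrow(f1))) {
      gap <- abs(f2$diversity - f1$diversity[r]) +
        abs(f2$dispersion - f1$dispersion[r])
      expect_lt(min(gap), 1e-9)
    }
    if (nrow(f1) == nrow(f2) &&
        max(abs(as.matrix(f1) - as.matrix(f2))) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.95)
})

test_that("diversity and dispersion can be scored on two different matrices", {
  set.seed(67)
  words <- replicate(12, paste(sample(letters[1:6], sample(3:8, 1),
                                      replace = TRUE), collapse = ""))
  D_disp <- levenshtein_matrix(words)              # orthographic dissimilarity
  D_div <- distance_matrix(matrix(rnorm(36), 12))  # covariate balance
  sizes <- rep(4, 3)
  opt <- optimal_dispersion(D_disp, 3, sizes)
  S <- bils(D_div, D_disp, K = 3, sizes = sizes,
            bils_config(20, 10, init = "hybrid-all"), opt = opt)
  for (e in S$entries) {
    expect_equal(e$diversity, diversity(D_div, e$partition), tolerance = 1e-9)
    expect_equal(e$dispersion, dispersion(D_disp, e$partition))
  }
  expect_equal(select_entry(S, "max-dispersion")$dispersion, opt$dispersion)
  e2 <- restricted_lcw(D_div, D_disp, K = 3, sizes = sizes, opt = opt)
  expect_equal(e2$dispersion, opt$dispersion)
  expect_equal(e2$diversity, diversity(D_div, e2$partition))
})

test_that("multistart bpi accumulates one deduplicated Pareto set", {
  set.seed(65)
  S <- mbpi(d4, d4, K = 2, restarts = 10)
  expect_equal(length(S), 1L)
  expect_equal(S$entries[[1]]$diversity, 7)
  set.seed(66); a <- mbpi(d4, d4, K = 2, restarts = 5)
  set.seed(66); b <- mbpi(d4, d4, K = 2, restarts = 5)
  expect_identical(lapply(a$entries, `[[`, "partition"),
                   lapply(b$entries, `[[`, "partition"))
})
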