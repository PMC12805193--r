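# Exact bicriterion constraint method: maximize diversity subject to a
# dispersion floor, implemented through a penalty-adjusted dissimilarity
# matrix, and the exact Pareto frontier obtained by sweeping the floor.

penalty_for <- function(D) sum(D[upper.tri(D)]) + 1

# forbid pairs whose value in `Dref` falls strictly below `threshold` by
# writing a large negative penalty into `D` (penalty sized from `D` itself,
# so a single forbidden pair outweighs all attainable diversity)
adjust_cross <- function(D, Dref, threshold) {
  M <- penalty_for(D)
  forbid <- Dref < threshold & upper.tri(Dref)
  forbid <- forbid | t(forbid)
  A <- D
  A[forbid] <- -M
  diag(A) <- 0
  attr(A, "flavor") <- "adjusted"
  attr(A, "threshold") <- threshold
  attr(A, "penalty") <- M
  A
}

#' Penalty-adjust a dissimilarity matrix to induce cannot-link constraints
#'
#' Pairs with dissimilarity strictly below `threshold` are set to a large
#' negative penalty `-M`, with `M` one more than the sum of all pairwise
#' dissimilarities.  Any partition grouping a forbidden pair then scores
#' below every partition that avoids all forbidden pairs, so maximizing the
#' diversity on the adjusted matrix enforces the constraints.  The strict
#' inequality keeps partitions that *attain* the threshold feasible, which
#' matches the dispersion being an attained minimum.
#'
#' @param D raw dissimilarity matrix.
#' @param threshold forbid pairs with `D < threshold`.
#' @return the adjusted matrix (flavor attribute `"adjusted"`).
#' @export
adjust_dissimilarities <- function(D, threshold) {
  D <- check_dissimilarity(D)
  adjust_cross(D, D, threshold)
}

#' Exact maximum-diversity partition
#'
#' Maximizes the within-group sum of dissimilarities over all partitions
#' with the given group sizes, by exact branch-and-bound over assignments.
#' Accepts raw or penalty-adjusted matrices.  Exceeding the search budget
#' raises an error of class `antipart_solver_limit` carrying the best
#' incumbent found (`condition$incumbent`).
#'
#' @param D dissimilarity matrix (raw or adjusted).
#' @param sizes group sizes summing to `nrow(D)`.
#' @param node_limit branch-and-bound node budget.
#' @return integer partition in canonical form.
#' @export
optimal_diversity <- function(D, sizes, node_limit = 1e8) {
  D <- check_dissimilarity(D, allow_adjusted = TRUE)
  sizes <- as.integer(sizes)
  if (sum(sizes) != nrow(D)) stop("sizes must sum to the number of objects")
  res <- max_diversity_bb_cpp(D, sizes, node_limit)
  if (res$status == -1L)
    stop_classed("antipart_solver_limit",
                 "diversity search budget exhausted; raise node_limit",
                 incumbent = res$assignment)
  canonical_clusters(res$assignment)
}

#' Exact bicriterion optimum: maximum diversity at optimal dispersion
#'
#' First determines the optimal dispersion, then maximizes the diversity
#' among all partitions attaining it, by forbidding (via the penalty
#' adjustment) every pair whose dissimilarity lies strictly below the
#' optimum.  Scores of the returned entry are computed on the raw matrix.
#'
#' @param D raw dissimilarity matrix.
#' @param K number of groups.
#' @param sizes group sizes summing to `nrow(D)`.
#' @param node_limit search budget for the exact solvers.
#' @return a [pareto_entry()].
#' @export
optimal_bicriterion <- function(D, K, sizes, node_limit = 1e8) {
  D <- check_dissimilarity(D)
  opt <- optimal_dispersion(D, K, sizes, node_limit)
  if (is.infinite(opt$dispersion)) {
    part <- complete_partition(opt)
    return(pareto_entry(part, diversity(D, part), dispersion(D, part)))
  }
  A <- adjust_dissimilarities(D, opt$dispersion)
  part <- optimal_diversity(A, sizes, node_limit)
  pareto_entry(part, diversity(D, part), dispersion(D, part))
}

#' Exact Pareto frontier of diversity and dispersion
#'
#' For every distinct dissimilarity value `t` up to the optimal dispersion
#' (descending), maximizes the diversity on the matrix adjusted at threshold
#' `t`, i.e. among partitions with dispersion at least `t`.  Entries are
#' scored on the raw matrix, deduplicated by canonical partition, and
#' filtered to the non-dominated set, which is the exact frontier.  The
#' sweep stops once the unconstrained diversity optimum is reached, since
#' relaxing the floor further cannot improve diversity.
#'
#' @inheritParams optimal_bicriterion
#' @return a [pareto_set()] (dispersion-sorted on printing).
#' @export
exact_pareto_set <- function(D, K, sizes, node_limit = 1e8) {
  D <- check_dissimilarity(D)
  opt <- optimal_dispersion(D, K, sizes, node_limit)
  if (is.infinite(opt$dispersion)) {
    part <- complete_partition(opt)
    return(pareto_set(list(
      pareto_entry(part, diversity(D, part), dispersion(D, part)))))
  }
  part_free <- optimal_diversity(D, sizes, node_limit)
  best_free <- diversity(D, part_free)
  entries <- list(pareto_entry(part_free, best_free, dispersion(D, part_free)))
  grid <- sort(unique(D[upper.tri(D)]), decreasing = TRUE)
  grid <- grid[grid <= opt$dispersion]
  for (t in grid) {
    part <- optimal_diversity(adjust_cross(D, D, t), sizes, node_limit)
    entries <- c(entries, list(
      pareto_entry(part, diversity(D, part), dispersion(D, part))))
    if (diversity(D, part) >= best_free) break
  }
  pareto_set(entries)
}
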