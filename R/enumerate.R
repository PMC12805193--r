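# Brute-force enumeration oracles used to certify the exact algorithms on
# small instances.

#' Enumerate all partitions with fixed group sizes
#'
#' Lists every distinct partition of `sum(sizes)` objects into groups of the
#' given sizes, treating groups of equal size as unlabeled: a group may only
#' be "opened" by the first empty slot within its size class, so every
#' partition appears exactly once (in canonical form).
#'
#' @param sizes integer group sizes.
#' @return integer matrix, one canonical assignment per row.
#' @export
enumerate_partitions <- function(sizes) {
  sizes <- as.integer(sizes)
  N <- sum(sizes); K <- length(sizes)
  counts <- integer(K)
  assign <- integer(N)
  res <- vector("list", 0L)
  rec <- function(i) {
    if (i > N) {
      res[[length(res) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (k in seq_len(K)) {
      if (counts[k] >= sizes[k]) next
      if (counts[k] == 0L &&
          which(counts == 0L & sizes == sizes[k])[1L] != k) next
      counts[k] <<- counts[k] + 1L
      assign[i] <<- k
      rec(i + 1L)
      counts[k] <<- counts[k] - 1L
    }
  }
  rec(1L)
  do.call(rbind, res)
}

#' Exhaustive search oracle
#'
#' Enumerates every partition with the given sizes and returns the exact
#' maximum diversity, maximum dispersion, and the exact Pareto frontier of
#' the two criteria.  Refuses instances whose partition space exceeds
#' `limit`.
#'
#' @param D raw dissimilarity matrix.
#' @param sizes group sizes summing to `nrow(D)`.
#' @param limit maximal number of partitions that will be enumerated.
#' @return list with `max_diversity`, `max_dispersion`,
#'   `best_diversity_at_max_dispersion`, `pareto` (a [pareto_set()]) and
#'   `n_partitions`.
#' @export
exhaustive_search <- function(D, sizes, limit = 1e6) {
  D <- check_dissimilarity(D)
  sizes <- as.integer(sizes)
  stopifnot(sum(sizes) == nrow(D))
  count <- prod(choose(cumsum(sizes), sizes)) /
    prod(factorial(table(sizes)))
  if (count > limit)
    stop("partition space too large for exhaustive enumeration")
  parts <- enumerate_partitions(sizes)
  dv <- apply(parts, 1L, function(p) diversity(D, p))
  ds <- apply(parts, 1L, function(p) dispersion(D, p))
  S <- pareto_set()
  for (i in seq_len(nrow(parts)))
    S <- pareto_update(S, pareto_entry(parts[i, ], dv[i], ds[i]))
  list(max_diversity = max(dv),
       max_dispersion = max(ds),
       best_diversity_at_max_dispersion = max(dv[ds == max(ds)]),
       pareto = S,
       n_partitions = nrow(parts))
}
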