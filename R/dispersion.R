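# Exact maximum dispersion: ascending threshold sweep over the distinct
# dissimilarity values, testing at each step whether the graph of
# "must-not-link" pairs admits a coloring that respects the group sizes.

#' Cannot-link graph at a dissimilarity threshold
#'
#' Connects every pair of objects whose dissimilarity is at or below
#' `threshold`; such pairs must end up in different groups for the partition
#' dispersion to exceed the threshold.
#'
#' @param D raw dissimilarity matrix.
#' @param threshold numeric cutoff.
#' @return an object of class `cannot_link_graph` with fields `n` and
#'   `edges` (a two-column matrix of 1-based vertex pairs).
#' @export
cannot_link_graph <- function(D, threshold) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  idx <- which(upper.tri(D) & D <= threshold, arr.ind = TRUE)
  structure(list(n = n, edges = unname(idx)), class = "cannot_link_graph")
}

edge_graph <- function(n, edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(0), 0L, 2L)
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n)) stop("edge endpoints out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  }
  structure(list(n = n, edges = edges), class = "cannot_link_graph")
}

#' Cardinality-bounded K-coloring of a cannot-link graph
#'
#' Decides whether the vertices can be assigned to `K` groups such that
#' adjacent vertices are separated and group `k` receives at most `sizes[k]`
#' vertices (isolated vertices are left unassigned; they can absorb any
#' remaining capacity).  Infeasibility is an ordinary verdict; exhausting
#' the search budget raises an error of class `antipart_solver_limit`, which
#' is never conflated with infeasibility.
#'
#' @param graph a [cannot_link_graph()].
#' @param K number of groups.
#' @param sizes group capacities (defaults to unbounded, i.e. plain
#'   K-colorability).
#' @param node_limit search-node budget for the exact backtracking solver.
#' @return list with `feasible` (logical) and, when feasible, `coloring`
#'   (1-based group labels, `NA` for unassigned vertices).
#' @export
k_color_with_cardinalities <- function(graph, K, sizes = NULL,
                                       node_limit = 1e7) {
  stopifnot(inherits(graph, "cannot_link_graph"))
  caps <- if (is.null(sizes)) rep(graph$n, K) else as.integer(sizes)
  if (length(caps) != K) stop("sizes must have length K")
  ed <- graph$edges - 1L
  res <- color_bounded_cpp(graph$n, ed, as.integer(K), caps, node_limit)
  if (res$status == -1L)
    stop_classed("antipart_solver_limit",
                 "coloring search budget exhausted; raise node_limit")
  if (res$status == 1L)
    validate_coloring(res$coloring, graph$edges, caps)
  list(feasible = res$status == 1L,
       coloring = if (res$status == 1L) res$coloring else NULL)
}

# a feasibility verdict must come with a checkable certificate
validate_coloring <- function(coloring, edges, caps) {
  if (nrow(edges)) {
    a <- coloring[edges[, 1L]]
    b <- coloring[edges[, 2L]]
    if (anyNA(a) || anyNA(b) || any(a == b))
      stop_classed("antipart_internal",
                   "solver returned an invalid coloring certificate")
  }
  usage <- tabulate(coloring[!is.na(coloring)], nbins = length(caps))
  if (any(usage > caps))
    stop_classed("antipart_internal",
                 "solver certificate violates the capacity bounds")
  invisible(TRUE)
}

#' Exact maximum dispersion under cardinality constraints
#'
#' Sweeps the distinct dissimilarity values in ascending order.  At each
#' threshold, all pairs at or below it are connected in a cannot-link graph
#' and a cardinality-bounded coloring decides whether they can still be
#' separated into the K groups.  The largest feasible threshold certifies
#' the optimum: the maximum attainable dispersion is the next higher
#' dissimilarity value.  Tied dissimilarity values are processed as a single
#' step, so input order of tied pairs is irrelevant.
#'
#' @param D raw dissimilarity matrix.
#' @param K number of groups.
#' @param sizes group sizes summing to `nrow(D)`; `NULL` leaves the group
#'   sizes free (only the number of groups is fixed).
#' @param node_limit search budget per feasibility test.
#' @return an object of class `optimal_dispersion`: a list with
#'   `dispersion` (the optimum; `Inf` when no two objects are forced to
#'   share a group), `theta_star` (largest feasible threshold; `NA` if even
#'   the smallest dissimilarity cannot be separated), `partial` (group
#'   labels for the vertices that certify the optimum, `NA` elsewhere), and
#'   the instance description (`n`, `K`, `sizes`).
#' @seealso [complete_partition()] to extend `partial` to a full partition.
#' @export
optimal_dispersion <- function(D, K, sizes = NULL, node_limit = 1e7) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  K <- as.integer(K)
  if (!is.null(sizes)) {
    sizes <- as.integer(sizes)
    if (length(sizes) != K || sum(sizes) != n)
      stop("sizes must have length K and sum to the number of objects")
    if (any(sizes < 1L)) stop("all group sizes must be positive")
  }
  out <- structure(list(dispersion = Inf, theta_star = NA_real_,
                        partial = rep(NA_integer_, n),
                        n = n, K = K, sizes = sizes),
                   class = "optimal_dispersion")
  if (!is.null(sizes) && all(sizes == 1L)) {   # all-singleton: vacuous minimum
    out$partial <- seq_len(n)
    return(out)
  }
  iu <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[iu]
  ord <- order(dv, iu[, 1L], iu[, 2L])
  dv <- dv[ord]; iu <- iu[ord, , drop = FALSE]
  grid <- unique(dv)
  caps <- if (is.null(sizes)) rep(n, K) else sizes
  edges <- matrix(integer(0), 0L, 2L)
  upto <- 0L
  for (t in seq_along(grid)) {
    take <- which(dv == grid[t])
    edges <- rbind(edges, iu[take, , drop = FALSE])
    res <- color_bounded_cpp(n, edges - 1L, K, as.integer(caps), node_limit)
    if (res$status == -1L)
      stop_classed("antipart_solver_limit",
                   "coloring search budget exhausted; raise node_limit")
    if (res$status == 1L) {
      validate_coloring(res$coloring, edges, caps)
      out$theta_star <- grid[t]
      out$partial <- res$coloring
    } else {
      out$dispersion <- grid[t]
      return(out)
    }
  }
  out  # full graph separable: dispersion unbounded (n <= K)
}

#' @export
print.optimal_dispersion <- function(x, ...) {
  cat(sprintf("optimal dispersion: %s (largest separable threshold: %s)\n",
              format(x$dispersion), format(x$theta_star)))
  cat(sprintf("%d of %d objects fixed by the certificate\n",
              sum(!is.na(x$partial)), x$n))
  invisible(x)
}

#' Complete a partial optimal-dispersion assignment
#'
#' Objects that the dispersion certificate leaves unassigned can be placed
#' arbitrarily without changing the dispersion; this fills them uniformly at
#' random among the remaining group capacities.  Different calls (with
#' different RNG states) can therefore yield different partitions, all with
#' optimal dispersion.
#'
#' @param res an [optimal_dispersion()] result obtained with explicit sizes.
#' @return a full integer partition respecting the cardinality constraints.
#' @export
complete_partition <- function(res) {
  stopifnot(inherits(res, "optimal_dispersion"))
  if (is.null(res$sizes))
    stop("completion requires fixed group sizes")
  part <- res$partial
  counts <- tabulate(part[!is.na(part)], nbins = res$K)
  remaining <- res$sizes - counts
  if (any(remaining < 0L))
    stop_classed("antipart_internal", "certificate exceeds group capacities")
  free <- which(is.na(part))
  if (length(free)) {
    slots <- rep.int(seq_len(res$K), remaining)
    part[free] <- slots[sample.int(length(slots))]
  }
  as.integer(part)
}

#' Partition under general cannot-link constraints
#'
#' Separates every listed pair of objects into different groups while
#' respecting the cardinality constraints; objects not constrained are
#' assigned at random among the remaining capacity.  An unsatisfiable
#' constraint set raises an error of class `antipart_infeasible`.
#'
#' @param pairs two-column matrix (or data frame) of 1-based object indices
#'   that must not share a group; may have zero rows.
#' @param N number of objects.
#' @param K number of groups.
#' @param sizes group sizes summing to `N`.
#' @param node_limit search budget for the feasibility solver.
#' @return integer partition of length `N`.
#' @export
satisfy_cannot_link <- function(pairs, N, K, sizes, node_limit = 1e7) {
  N <- as.integer(N); K <- as.integer(K)
  sizes <- as.integer(sizes)
  if (sum(sizes) != N || length(sizes) != K)
    stop("sizes must have length K and sum to N")
  g <- edge_graph(N, pairs)
  res <- k_color_with_cardinalities(g, K, sizes, node_limit)
  if (!res$feasible)
    stop_classed("antipart_infeasible",
                 "the cannot-link constraints cannot be satisfied")
  fake <- structure(list(dispersion = NA_real_, theta_star = NA_real_,
                         partial = res$coloring, n = N, K = K, sizes = sizes),
                    class = "optimal_dispersion")
  complete_partition(fake)
}
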