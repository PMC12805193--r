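# Pareto-dominance bookkeeping over (diversity, dispersion) score pairs.

#' Canonical form of a cluster assignment
#'
#' Relabels clusters in order of their first occurrence (equivalently, the
#' smallest member index), so that two assignments describe the same
#' partition exactly when their canonical forms are identical.
#'
#' @param clusters integer vector of cluster assignments.
#' @return integer vector with clusters relabeled 1, 2, ...
#' @export
canonical_clusters <- function(clusters) {
  match(clusters, unique(clusters))
}

#' Create a Pareto entry
#'
#' Bundles a partition with its diversity and dispersion scores.  The
#' partition is stored in canonical form; scores are expected to be computed
#' on the raw dissimilarity matrices.
#'
#' @param partition integer cluster assignment.
#' @param diversity,dispersion the two criterion scores.
#' @export
pareto_entry <- function(partition, diversity, dispersion) {
  structure(list(partition = canonical_clusters(as.integer(partition)),
                 diversity = as.numeric(diversity),
                 dispersion = as.numeric(dispersion)),
            class = "pareto_entry")
}

#' Pareto dominance between two entries
#'
#' `a` dominates `b` when `a` is at least as good on both criteria and
#' strictly better on at least one.  Comparisons are exact on the stored
#' scores.
#'
#' @param a,b objects created by [pareto_entry()].
#' @return logical.
#' @export
dominates <- function(a, b) {
  (a$diversity >= b$diversity && a$dispersion >= b$dispersion) &&
    (a$diversity > b$diversity || a$dispersion > b$dispersion)
}

#' Create a Pareto set
#'
#' @param entries optional list of [pareto_entry()] objects; they are folded
#'   in through [pareto_update()], so the result is always non-dominated.
#' @export
pareto_set <- function(entries = list()) {
  S <- structure(list(entries = list()), class = "pareto_set")
  for (e in entries) S <- pareto_update(S, e)
  S
}

#' Update a Pareto set with a candidate entry
#'
#' The candidate is inserted unless some member dominates it or an identical
#' partition is already present; members dominated by the candidate are
#' removed.  The operation is idempotent and insensitive to the order in
#' which a stream of candidates arrives.
#'
#' @param S a [pareto_set()].
#' @param entry a [pareto_entry()].
#' @export
pareto_update <- function(S, entry) {
  stopifnot(inherits(S, "pareto_set"), inherits(entry, "pareto_entry"))
  for (e in S$entries) {
    if (dominates(e, entry)) return(S)
    if (e$diversity == entry$diversity && e$dispersion == entry$dispersion &&
        identical(e$partition, entry$partition)) return(S)
  }
  S$entries <- Filter(function(e) !dominates(entry, e), S$entries)
  S$entries <- c(S$entries, list(entry))
  S
}

#' Select a partition from a Pareto set
#'
#' @param S a nonempty [pareto_set()].
#' @param rule `"max-dispersion"` picks the entry with the highest
#'   dispersion, ties broken by higher diversity; `"max-diversity"` is the
#'   symmetric rule.
#' @return a [pareto_entry()].
#' @export
select_entry <- function(S, rule = c("max-dispersion", "max-diversity")) {
  rule <- match.arg(rule)
  if (!inherits(S, "pareto_set") || length(S$entries) == 0L)
    stop("the Pareto set is empty")
  dv <- vapply(S$entries, `[[`, numeric(1), "diversity")
  ds <- vapply(S$entries, `[[`, numeric(1), "dispersion")
  i <- if (rule == "max-dispersion") {
    order(-ds, -dv)[1L]
  } else {
    order(-dv, -ds)[1L]
  }
  S$entries[[i]]
}

#' @export
length.pareto_set <- function(x) length(x$entries)

#' @export
as.data.frame.pareto_set <- function(x, ...) {
  data.frame(
    diversity = vapply(x$entries, `[[`, numeric(1), "diversity"),
    dispersion = vapply(x$entries, `[[`, numeric(1), "dispersion"))
}

#' @export
print.pareto_set <- function(x, ...) {
  cat("Pareto set with", length(x$entries), "partition(s)\n")
  if (length(x$entries)) {
    df <- as.data.frame(x)
    print(df[order(-df$dispersion), ], ...)
  }
  invisible(x)
}

#' @export
print.pareto_entry <- function(x, ...) {
  cat(sprintf("partition into %d groups: diversity %.6g, dispersion %.6g\n",
              length(unique(x$partition)), x$diversity, x$dispersion))
  invisible(x)
}
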