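# Criterion computations: diversity, average diversity, k-means/k-plus,
# dispersion, and the dissimilarity constructors they operate on.

check_features <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("feature matrix must be numeric")
  if (nrow(X) < 2L) stop("need at least two objects")
  if (any(!is.finite(X))) stop("feature matrix contains non-finite entries")
  X
}

check_dissimilarity <- function(D, allow_adjusted = FALSE) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (any(!is.finite(D))) stop("dissimilarity matrix contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("dissimilarity matrix must have a zero diagonal")
  adjusted <- identical(attr(D, "flavor"), "adjusted")
  if (!adjusted && any(D < 0))
    stop("raw dissimilarity matrices must be nonnegative")
  if (adjusted && !allow_adjusted)
    stop("a raw (unadjusted) dissimilarity matrix is required here")
  D
}

check_clusters <- function(clusters, n, sizes = NULL) {
  clusters <- as.integer(clusters)
  if (length(clusters) != n)
    stop("partition length does not match the number of objects")
  if (anyNA(clusters)) stop("partition contains missing assignments")
  if (!is.null(sizes)) {
    tab <- tabulate(clusters, nbins = length(sizes))
    if (!all(tab == sizes)) stop("partition violates the cardinality constraints")
  }
  clusters
}

#' Pairwise dissimilarity matrix from a feature matrix
#'
#' Computes the full symmetric matrix of pairwise dissimilarities between the
#' rows of `X`.  The squared Euclidean distance is the default because it
#' links the diversity criterion to the k-means criterion (see
#' [kmeans_criterion()]).
#'
#' @param X numeric feature matrix (objects in rows).
#' @param method one of `"squared-euclidean"`, `"euclidean"`, `"manhattan"`.
#' @return an N x N symmetric numeric matrix with zero diagonal.
#' @examples
#' X <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
#' distance_matrix(X)[1, 2]  # 25
#' @export
distance_matrix <- function(X, method = c("squared-euclidean", "euclidean",
                                          "manhattan")) {
  method <- match.arg(method)
  X <- check_features(X)
  d <- switch(method,
    "squared-euclidean" = as.matrix(dist(X, method = "euclidean"))^2,
    "euclidean" = as.matrix(dist(X, method = "euclidean")),
    "manhattan" = as.matrix(dist(X, method = "manhattan")))
  dimnames(d) <- list(rownames(X), rownames(X))
  diag(d) <- 0
  d
}

#' Normalized Levenshtein dissimilarity between strings
#'
#' For strings `s_i`, `s_j` with unit-cost edit distance `L`, the normalized
#' distance is `2 L / (|s_i| + |s_j| + L)`, a metric bounded by 1.  Useful
#' for quantifying orthographic dissimilarity of word stimuli.
#'
#' @param words character vector of nonempty strings.
#' @return symmetric matrix of normalized edit distances in `[0, 1]`.
#' @examples
#' levenshtein_matrix(c("a", "b"))[1, 2]   # 2/3
#' levenshtein_matrix(c("ab", "a"))[1, 2]  # 0.5
#' @export
levenshtein_matrix <- function(words) {
  words <- as.character(words)
  if (length(words) < 2L) stop("need at least two strings")
  if (any(is.na(words)) || any(!nzchar(words)))
    stop("strings must be nonempty")
  L <- utils::adist(words)
  den <- outer(nchar(words), nchar(words), `+`) + L
  d <- ifelse(den == 0, 0, 2 * L / den)
  diag(d) <- 0
  dimnames(d) <- list(words, words)
  d
}

#' Augment features with squared-deviation columns (k-plus)
#'
#' Appends, for every feature `j`, the column of squared deviations from its
#' overall mean.  Maximizing a k-means-type criterion on the augmented matrix
#' equates group variances in addition to group means.
#'
#' @param X numeric feature matrix.
#' @param moments number of moments to equate; only `2` (means + variances)
#'   is supported.
#' @return a matrix with `2 * ncol(X)` columns.
#' @export
kplus_augment <- function(X, moments = 2L) {
  X <- check_features(X)
  if (!identical(as.integer(moments), 2L))
    stop("only moments = 2 (means and variances) is supported")
  dev2 <- sweep(X, 2L, colMeans(X))^2
  colnames(dev2) <- if (!is.null(colnames(X))) paste0(colnames(X), "_dev2")
  cbind(X, dev2)
}

#' Diversity: within-group sum of pairwise dissimilarities
#'
#' Each unordered within-group pair is counted once.  Maximizing the
#' diversity makes the groups similar to each other at the aggregate level.
#'
#' @param D symmetric dissimilarity matrix.
#' @param clusters integer vector of cluster assignments (1-based).
#' @return a single number.
#' @export
diversity <- function(D, clusters) {
  D <- check_dissimilarity(D, allow_adjusted = TRUE)
  clusters <- check_clusters(clusters, nrow(D))
  s <- 0
  for (idx in split(seq_len(nrow(D)), clusters))
    if (length(idx) > 1L) s <- s + sum(D[idx, idx]) / 2
  s
}

#' Average diversity: per-cluster-size-normalized diversity
#'
#' Divides each cluster's within-group sum by its cardinality before adding
#' up.  With squared Euclidean dissimilarities this equals the k-means
#' criterion for any group sizes; with equal sizes it is `diversity / n_k`.
#'
#' @inheritParams diversity
#' @export
average_diversity <- function(D, clusters) {
  D <- check_dissimilarity(D, allow_adjusted = TRUE)
  clusters <- check_clusters(clusters, nrow(D))
  s <- 0
  for (idx in split(seq_len(nrow(D)), clusters))
    if (length(idx) > 1L) s <- s + sum(D[idx, idx]) / 2 / length(idx)
  s
}

#' k-means criterion (within-cluster sum of squares)
#'
#' Sum of squared Euclidean distances between each object and its cluster
#' centroid.  Maximizing it pulls all cluster centroids toward the global
#' centroid, i.e. equates group means.
#'
#' @param X numeric feature matrix.
#' @param clusters integer vector of cluster assignments.
#' @export
kmeans_criterion <- function(X, clusters) {
  X <- check_features(X)
  clusters <- check_clusters(clusters, nrow(X))
  s <- 0
  for (idx in split(seq_len(nrow(X)), clusters)) {
    Xi <- X[idx, , drop = FALSE]
    s <- s + sum(sweep(Xi, 2L, colMeans(Xi))^2)
  }
  s
}

#' Dispersion: worst-case within-group dissimilarity
#'
#' The minimum dissimilarity over all pairs of objects sharing a group.  For
#' an all-singleton partition the minimum is vacuous and `Inf` is returned,
#' so that Pareto bookkeeping degrades gracefully.
#'
#' @inheritParams diversity
#' @export
dispersion <- function(D, clusters) {
  D <- check_dissimilarity(D, allow_adjusted = TRUE)
  clusters <- check_clusters(clusters, nrow(D))
  m <- Inf
  for (idx in split(seq_len(nrow(D)), clusters))
    if (length(idx) > 1L) {
      Di <- D[idx, idx]
      m <- min(m, min(Di[upper.tri(Di)]))
    }
  m
}

# --- exact partition counting (arbitrary precision) ------------------------
# Small base-1e7 bignum: numeric digit vectors, least significant first.

big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  digits <- numeric(0)
  while (x > 0) {
    digits <- c(digits, x %% 1e7)
    x <- x %/% 1e7
  }
  digits
}

big_mul_small <- function(b, m) {
  carry <- 0
  for (i in seq_along(b)) {
    v <- b[i] * m + carry
    b[i] <- v %% 1e7
    carry <- v %/% 1e7
  }
  while (carry > 0) {
    b <- c(b, carry %% 1e7)
    carry <- carry %/% 1e7
  }
  b
}

big_div_small <- function(b, m) {
  rem <- 0
  for (i in rev(seq_along(b))) {
    v <- rem * 1e7 + b[i]
    b[i] <- v %/% m
    rem <- v %% m
  }
  stopifnot(rem == 0)  # all divisions in the counting formula are exact
  while (length(b) > 1L && b[length(b)] == 0) b <- b[-length(b)]
  b
}

big_to_string <- function(b) {
  out <- format(b[length(b)], scientific = FALSE)
  if (length(b) > 1L)
    out <- paste0(out, paste(sprintf("%07d", rev(b[-length(b)])), collapse = ""))
  out
}

#' Number of partitions into K equal-sized unlabeled groups
#'
#' Exact count of the distinct ways to split `N` objects into `K` groups of
#' `N / K` objects each, with interchangeable group labels:
#' `N! / ((N/K)!^K * K!)`.  Evaluated in exact integer arithmetic and
#' returned as a digit string, since the count overflows doubles quickly.
#'
#' @param N number of objects; must be divisible by `K`.
#' @param K number of groups.
#' @return the exact count as a character string of decimal digits.
#' @examples
#' partition_count(4, 2)   # "3"
#' partition_count(30, 3)  # "925166131890"
#' @export
partition_count <- function(N, K) {
  N <- as.integer(N); K <- as.integer(K)
  if (K < 1L || N < 1L || N %% K != 0L)
    stop("K must be a positive divisor of N")
  n <- N %/% K
  b <- big_from_int(1)
  for (k in seq_len(K)) {        # product of C(k*n, n)
    m <- k * n
    for (i in seq_len(n)) {      # C(m, n) built incrementally, always integral
      b <- big_mul_small(b, m - n + i)
      b <- big_div_small(b, i)
    }
  }
  for (k in seq_len(K)) b <- big_div_small(b, k)
  big_to_string(b)
}
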