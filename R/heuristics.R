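# Heuristic family: pairwise-interchange local search (LCW), its
# dispersion-preserving restriction, the bicriterion variant with Pareto
# bookkeeping (BPI), multistart (MBPI), perturbation (ILS) and the combined
# BILS with vanilla or hybrid initialization.

#' The ten admissible bicriterion weights
#'
#' Spanning twelve orders of magnitude, the catalog covers the scale
#' mismatch between the diversity (a sum over pairs) and the dispersion (a
#' single dissimilarity value) without explicit normalization.
#' @export
bils_weight_catalog <- c(0.000001, 0.00001, 0.0001, 0.001, 0.01, 0.1,
                         0.5, 0.99, 0.999, 0.999999)

#' Weighted bicriterion score
#'
#' `w * diversity + (1 - w) * dispersion`; the boundary weights return the
#' pure criteria so that an infinite dispersion sentinel never contaminates
#' a pure-diversity search.
#'
#' @param div,disp criterion values.
#' @param w weight in `[0, 1]`.
#' @export
weighted_bicriterion <- function(div, disp, w) {
  stopifnot(w >= 0, w <= 1)
  if (w >= 1) return(div)
  if (w <= 0) return(disp)
  w * div + (1 - w) * disp
}

#' Random partition with fixed group sizes
#'
#' @param sizes integer group sizes.
#' @return integer assignment of `sum(sizes)` objects.
#' @export
random_partition <- function(sizes) {
  slots <- rep.int(seq_along(sizes), sizes)
  slots[sample.int(length(slots))]
}

crit_code <- function(objective) {
  match.arg(objective, c("diversity", "average-diversity"))
  if (objective == "average-diversity") 1L else 0L
}

#' Pairwise-interchange local search (LCW)
#'
#' Best-improvement 2-swap search: for each object in turn, every exchange
#' with an object from a different cluster is evaluated and the best
#' strictly improving one is realized (ties broken by the lowest partner
#' index); full passes repeat until no exchange improves the objective.
#' Group sizes are preserved throughout.
#'
#' @param D dissimilarity matrix (raw or penalty-adjusted).
#' @param init initial partition (defines the group sizes).
#' @param objective `"diversity"` or `"average-diversity"`.
#' @return a locally optimal partition.
#' @export
lcw <- function(D, init, objective = "diversity") {
  D <- check_dissimilarity(D, allow_adjusted = TRUE)
  init <- check_clusters(init, nrow(D))
  sizes <- tabulate(canonical_clusters(init))
  lcw_cpp(D, sizes, canonical_clusters(init), crit_code(objective))
}

#' Dispersion-preserving restricted LCW
#'
#' Initializes LCW with a completion of the optimal-dispersion certificate
#' and runs the search on a penalty-adjusted diversity matrix in which every
#' pair falling below the optimal dispersion (on the dispersion matrix) is
#' forbidden.  No accepted exchange can then break a forbidden pair, so the
#' result always retains the exact optimal dispersion.
#'
#' @param D_div dissimilarity matrix scored for diversity.
#' @param D_disp dissimilarity matrix scored for dispersion (defaults to
#'   `D_div`).
#' @param K,sizes group structure.
#' @param opt optional precomputed [optimal_dispersion()] result for
#'   `D_disp`.
#' @param init optional initial partition with optimal dispersion; defaults
#'   to a random completion of the certificate.
#' @param objective criterion passed to [lcw()].
#' @return a [pareto_entry()] scored on the raw matrices.
#' @export
restricted_lcw <- function(D_div, D_disp = D_div, K, sizes, opt = NULL,
                           init = NULL, objective = "diversity") {
  D_div <- check_dissimilarity(D_div)
  D_disp <- check_dissimilarity(D_disp)
  opt <- opt %||% optimal_dispersion(D_disp, K, sizes)
  init <- init %||% complete_partition(opt)
  part <- if (is.infinite(opt$dispersion)) {
    init
  } else {
    A <- adjust_cross(D_div, D_disp, opt$dispersion)
    lcw_cpp(A, as.integer(sizes), canonical_clusters(init),
            crit_code(objective))
  }
  pareto_entry(part, diversity(D_div, part), dispersion(D_disp, part))
}

#' Bicriterion pairwise interchange (BPI)
#'
#' LCW-style best-improvement search on the weighted bicriterion score,
#' recording every realized exchange (plus the initial and final partition)
#' in a Pareto set scored on the raw matrices.
#'
#' @param D_div,D_disp dissimilarity matrices for the two criteria.
#' @param w weight for the diversity criterion.
#' @param init initial partition.
#' @param S Pareto set carried across calls (default empty).
#' @param objective between-group criterion selector.
#' @return list with `partition` (the local optimum) and `pareto` (the
#'   updated [pareto_set()]).
#' @export
bpi <- function(D_div, D_disp = D_div, w, init, S = pareto_set(),
                objective = "diversity") {
  D_div <- check_dissimilarity(D_div)
  D_disp <- check_dissimilarity(D_disp)
  init <- check_clusters(init, nrow(D_div))
  sizes <- tabulate(canonical_clusters(init))
  res <- bpi_cpp(D_div, D_disp, sizes, canonical_clusters(init), w,
                 crit_code(objective),
                 lapply(S$entries, `[[`, "partition"),
                 vapply(S$entries, `[[`, numeric(1), "diversity"),
                 vapply(S$entries, `[[`, numeric(1), "dispersion"))
  list(partition = res$final, pareto = wrap_store(res))
}

wrap_store <- function(res) {
  S <- structure(list(entries = list()), class = "pareto_set")
  S$entries <- lapply(seq_along(res$partitions), function(e)
    structure(list(partition = res$partitions[[e]],
                   diversity = res$diversity[e],
                   dispersion = res$dispersion[e]),
              class = "pareto_entry"))
  S
}

#' ILS perturbation by random pair swaps
#'
#' Iterates over all unordered object pairs in fixed index order and swaps
#' the cluster assignments of each pair currently in different clusters
#' independently with probability `p`.  Group sizes are preserved.
#'
#' @param clusters integer partition.
#' @param p swap probability in `(0, 1)`.
#' @export
ils_perturb <- function(clusters, p) {
  stopifnot(p > 0, p < 1)
  ils_perturb_cpp(as.integer(clusters), p)
}

#' BILS configuration
#'
#' @param restarts_total total number of restarts.
#' @param restarts_ils how many of them run the perturbation phase (default
#'   half, matching the recommended split).
#' @param swap_prob_range interval from which the per-iteration swap
#'   probability is drawn uniformly.
#' @param init `"vanilla"` (random initial partitions), `"hybrid-1"` (first
#'   restart starts from an optimal-dispersion completion) or `"hybrid-all"`
#'   (every restart starts from a fresh completion).
#' @param objective between-group criterion optimized and bookkept.
#' @param weights weight catalog sampled per restart.
#' @export
bils_config <- function(restarts_total = 100L,
                        restarts_ils = restarts_total %/% 2L,
                        swap_prob_range = c(0.05, 0.10),
                        init = c("vanilla", "hybrid-1", "hybrid-all"),
                        objective = c("diversity", "average-diversity"),
                        weights = bils_weight_catalog) {
  init <- match.arg(init)
  objective <- match.arg(objective)
  stopifnot(restarts_total >= 1L, restarts_ils >= 0L,
            restarts_ils <= restarts_total,
            length(swap_prob_range) == 2L,
            all(swap_prob_range > 0), all(swap_prob_range < 1),
            diff(swap_prob_range) >= 0,
            all(weights >= 0), all(weights <= 1))
  structure(list(restarts_total = as.integer(restarts_total),
                 restarts_ils = as.integer(restarts_ils),
                 swap_prob_range = as.numeric(swap_prob_range),
                 init = init, objective = objective,
                 weights = as.numeric(weights)),
            class = "bils_config")
}

#' Bicriterion iterated local search (BILS)
#'
#' Phase 1 runs `restarts_total - restarts_ils` BPI restarts (with the
#' weight drawn from the catalog per restart); phase 2 runs `restarts_ils`
#' iterations that each pick a uniform-random Pareto entry, perturb it with
#' [ils_perturb()] (probability drawn uniformly from `swap_prob_range`),
#' and restore local optimality with BPI under a freshly drawn weight.  All
#' restarts share one Pareto set.  The hybrid initialization modes seed
#' phase 1 with optimal-dispersion completions, which guarantees that the
#' returned set contains an entry with exactly optimal dispersion.
#'
#' @param D_div,D_disp dissimilarity matrices for diversity and dispersion
#'   (a single matrix may serve both).
#' @param K number of groups.
#' @param sizes group sizes; defaults to an equal split when `K` divides N.
#' @param config a [bils_config()].
#' @param opt optional precomputed [optimal_dispersion()] result (used by
#'   the hybrid modes; computed on demand otherwise).
#' @return a [pareto_set()].
#' @export
bils <- function(D_div, D_disp = D_div, K, sizes = NULL,
                 config = bils_config(), opt = NULL) {
  D_div <- check_dissimilarity(D_div)
  D_disp <- check_dissimilarity(D_disp)
  n <- nrow(D_div)
  if (nrow(D_disp) != n) stop("the two matrices must agree on N")
  if (is.null(sizes)) {
    if (n %% K != 0L) stop("sizes must be given when K does not divide N")
    sizes <- rep.int(n %/% K, K)
  }
  sizes <- as.integer(sizes)
  stopifnot(sum(sizes) == n, length(sizes) == K)
  n1 <- config$restarts_total - config$restarts_ils
  if (n1 < 1L)
    stop("at least one restart must precede the perturbation phase")
  if (config$init != "vanilla")
    opt <- opt %||% optimal_dispersion(D_disp, K, sizes)
  inits <- matrix(0L, n1, n)
  for (r in seq_len(n1)) {
    inits[r, ] <- switch(config$init,
      "vanilla" = random_partition(sizes),
      "hybrid-1" = if (r == 1L) complete_partition(opt) else
        random_partition(sizes),
      "hybrid-all" = complete_partition(opt))
  }
  res <- bils_cpp(D_div, D_disp, sizes, inits, config$restarts_ils,
                  config$weights, config$swap_prob_range[1L],
                  config$swap_prob_range[2L],
                  crit_code(config$objective))
  wrap_store(res)
}

#' Multistart BPI (MBPI)
#'
#' BILS without the perturbation phase: repeated BPI restarts from random
#' (or hybrid) initial partitions with per-restart weights, accumulating one
#' shared Pareto set.
#'
#' @inheritParams bils
#' @param restarts number of BPI restarts.
#' @param init initialization mode, as in [bils_config()].
#' @param objective between-group criterion selector.
#' @export
mbpi <- function(D_div, D_disp = D_div, K, sizes = NULL, restarts = 100L,
                 init = "vanilla", objective = "diversity", opt = NULL) {
  bils(D_div, D_disp, K, sizes,
       bils_config(restarts_total = restarts, restarts_ils = 0L,
                   init = init, objective = objective),
       opt = opt)
}
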