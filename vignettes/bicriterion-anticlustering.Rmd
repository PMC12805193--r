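---
title: "Bicriterion anticlustering: models, algorithms, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bicriterion anticlustering: models, algorithms, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(antipart)
```

## The problem

Many study designs require splitting a pool of objects — word stimuli,
test items, participants, samples — into $K$ groups of fixed sizes
$n_1,\dots,n_K$ that are *equivalent* at the group level.  Anticlustering
formalizes this as maximizing a clustering criterion: where cluster analysis
makes groups compact and well separated, anticlustering makes them mutually
similar and internally heterogeneous.

Two criteria matter here.  Given pairwise dissimilarities $d_{ij}$ and a
partition $C = \{C_1,\dots,C_K\}$:

* the **diversity** $\sum_k \sum_{i<j \in C_k} d_{ij}$, whose maximization
  equates groups in the aggregate (each unordered pair counted once);
* the **dispersion** $\min_k \min_{i<j \in C_k} d_{ij}$, the worst-case
  dissimilarity of two objects sharing a group.

The diversity is a between-group balance measure; the dispersion guards
against placing two near-duplicates in the same group (for example two
easily confused words in the same stimulus list).  The two criteria are
complementary, and a partition that is excellent on one can be poor on the
other, hence the bicriterion treatment: the object of interest is the
Pareto set of partitions not dominated on the pair
(diversity, dispersion).

### Criterion identities

With squared Euclidean dissimilarities the diversity family is tied to the
k-means criterion (within-cluster sum of squares): the per-cluster sum of
pairwise squared distances equals cluster size times the within-cluster sum
of squares.  Consequently the **average diversity** — per-cluster sums
divided by the cluster size $n_k$ — equals the k-means criterion exactly,
for any group sizes:

```{r}
X <- matrix(rnorm(24), 8)
cl <- random_partition(c(3, 5))
kmeans_criterion(X, cl)
average_diversity(distance_matrix(X), cl)
```

This identity fixes the normalization of the average diversity: dividing
each cluster's sum by $n_k$ is the unique form for which it holds with
unequal sizes, and with equal sizes it reduces to `diversity / n`.  It also
means maximizing diversity on squared Euclidean distances performs k-means
anticlustering (equates group means), and doing so on a
`kplus_augment()`-ed feature matrix additionally equates group variances.

## Exact maximum dispersion

The dispersion criterion has special structure: requiring dispersion above a
threshold $\theta$ is exactly a set of *cannot-link constraints* on all
pairs with $d_{ij} \le \theta$.  The solver therefore sweeps the distinct
dissimilarity values in ascending order, each time adding the tied pairs as
edges of a conflict graph and asking whether the graph can be colored with
$K$ colors such that color $k$ is used at most $n_k$ times.  The largest
feasible threshold $\theta^\*$ certifies the optimum: the maximum attainable
dispersion is the next higher dissimilarity value, and the feasible coloring
at $\theta^\*$ is a *partial* partition — vertices not incident to any edge
may be placed arbitrarily (`complete_partition()`) without affecting the
dispersion.

Cardinality constraints change the answer, not just the difficulty.  On the
toy matrix with $d_{12}=1, d_{13}=2, \dots, d_{34}=6$, two free groups can
reach dispersion 4 (isolate object 1), but equal sizes (2, 2) cap it at 3:

```{r}
d4 <- matrix(0, 4, 4)
d4[1, 2] <- 1; d4[1, 3] <- 2; d4[1, 4] <- 3
d4[2, 3] <- 4; d4[2, 4] <- 5; d4[3, 4] <- 6
d4 <- d4 + t(d4)
optimal_dispersion(d4, 2)$dispersion        # 4: isolate object 1
optimal_dispersion(d4, 2, c(2, 2))$dispersion  # 3: equal sizes bind
```

### The bounded-coloring solver

No integer-programming backend is required: the cardinality-bounded
coloring feasibility problem is solved by an exact combinatorial search
written for the structure these sweeps produce (sparse, near-geometric
conflict graphs):

* $K = 2$ is polynomial: each connected component is two-colored by
  breadth-first search (an odd cycle proves infeasibility) and the
  orientation of the components is chosen by a subset-sum dynamic program
  over the side counts, which settles the capacities exactly.
* For $K \ge 3$, feasibility is usually certified first by a randomized
  capacity-aware greedy pass (DSATUR order, colors chosen by largest
  remaining capacity).  If that fails, infeasibility is attempted cheaply:
  a bounded clique search (a clique of $K+1$ vertices needs $K+1$ colors),
  then a plain-coloring test of the $K$-core (any witness of chromatic
  number $> K$ survives in the $K$-core; if the core is $K$-colorable the
  whole component is).  Only then runs the complete backtracking search:
  components are processed largest-first with suffix failures memoized on
  the sorted remaining capacities (components interact only through
  capacities); within a component the search branches DSATUR-style,
  unit-propagates vertices with a single allowed color, fails early when
  the vertices forced to one color exceed its remaining capacity, breaks
  the symmetry of colors that are unused in the component and have equal
  remaining capacity, and re-splits the uncolored remainder into connected
  parts as vertices are assigned.

The search is exact but guarded by a node budget.  Exceeding the budget
raises an error of class `antipart_solver_limit`; it is never reported as
"infeasible".  Worst-case instances exist — the problem is NP-hard for
$K \ge 3$, and open for $K = 2$ with cardinalities — but across the
synthetic design used in the benchmark below roughly one instance in
several hundred at $K = 5$ exhausts the default budget.

The same machinery exposes general cannot-link constraints: any list of
forbidden pairs becomes an edge set, and `satisfy_cannot_link()` returns a
satisfying partition or an `antipart_infeasible` error.

## The exact bicriterion constraint method

To maximize diversity among partitions that retain the optimal dispersion,
pairs with $d_{ij}$ *strictly below* the optimum are penalized: their
dissimilarity is replaced by $-M$ with $M$ one more than the sum of all
pairwise dissimilarities.  A single forbidden pair then costs more than all
attainable diversity, so the exact diversity maximizer avoids all forbidden
pairs whenever any separating partition exists — and one does, by the
dispersion certificate.  The strict inequality is essential: the partition
*attaining* the optimal dispersion must remain feasible, since the
dispersion is an attained minimum.  Any penalty larger than the distance
sum is behaviorally equivalent; the tests assert the behavior, not the
constant.

Maximum diversity itself is solved exactly by depth-first branch and bound
over assignments: objects are assigned in index order, a cluster may only
be "opened" by the first empty slot of its size class (groups of equal size
are unlabeled), candidate clusters are tried in order of immediate gain,
and a branch is cut when the current value plus the sum of the $F$ largest
pairwise values (with $F$ the number of within-group pairs still to be
formed) cannot beat the incumbent.  The bound is valid for raw and
penalty-adjusted matrices alike.  The method scales to the small-to-medium
instances the constraint method is meant for; beyond that it raises
`antipart_solver_limit` carrying the best incumbent.

Sweeping the constraint threshold over every distinct dissimilarity value
up to the optimal dispersion (descending), solving each adjusted problem,
rescoring on the raw matrix, deduplicating canonically and keeping the
non-dominated entries yields the exact Pareto frontier
(`exact_pareto_set()`).  The sweep stops once the unconstrained diversity
optimum is reached, since further relaxation cannot improve diversity.
Scores reported anywhere are always recomputed on the raw matrices; the
penalty never leaks into output.

## Heuristics with Pareto bookkeeping

For instances beyond exact reach the package implements a family of
pairwise-interchange searches.  All of them preserve the group sizes by
construction, since the only move is exchanging two objects between
clusters.

**LCW** is best-improvement 2-swap local search: for each object in turn,
all exchanges with objects in other clusters are evaluated and the best
strictly improving one realized, ties broken by the lowest partner index;
passes repeat until no exchange improves.  **BPI** applies the same scheme
to the weighted score $w \cdot \mathrm{diversity} + (1 - w) \cdot
\mathrm{dispersion}$ and, after every realized exchange, offers the current
partition to a shared Pareto set (scored on the raw matrices; each
restart's initial and final partitions are offered too — evaluated but
rejected neighbors are not recorded).  The weight is drawn per restart from
a ten-value catalog spanning $10^{-6}$ to $1 - 10^{-6}$; the extreme
values exist precisely because the two criteria live on different scales (a
sum over pairs versus a single dissimilarity), so no explicit normalization
is applied.  **MBPI** restarts BPI from random partitions; **BILS** adds an
iterated-local-search phase that picks a uniform-random Pareto entry,
swaps each eligible object pair independently with probability $p$ drawn
uniformly from $[0.05, 0.10]$, and restores local optimality with BPI
under a freshly drawn weight.  One phrasing question was settled as a
design choice: $p$ is drawn *once per perturbation*, then applied i.i.d.
per pair.

The candidate evaluation is incremental: cached object-to-cluster distance
sums give the diversity delta in $O(1)$, and the dispersion after a swap is
the minimum of the smallest surviving within-pair (from a sorted list) and
the new pairs formed by the two moved objects (from cached two-smallest
structures).  Entries inserted into the Pareto set are always rescored
exactly from the matrices, so stored scores equal recomputation.

### Hybrid initialization and the dispersion guarantee

Because the Pareto set never discards an entry unless a weakly better one
replaces it, seeding the search with a partition of *optimal* dispersion
guarantees the returned set contains an entry at exactly the optimum — a
dominating entry must itself have optimal dispersion.  Three modes:
`hybrid-1` seeds only the first restart with a certificate completion,
`hybrid-all` seeds every restart with a fresh random completion, `vanilla`
uses random partitions throughout.  **Restricted LCW** instead restricts
the search space: it runs plain LCW on the diversity matrix with all pairs
below the optimal dispersion penalty-adjusted, so no strictly improving
exchange can ever introduce a forbidden pair; its output provably retains
the optimal dispersion.

Diversity and dispersion may be scored on two different matrices (e.g.
feature-based balance for diversity, orthographic similarity for
dispersion); single-matrix calls alias both.  The between-group criterion
is selectable (`diversity` or `average-diversity`); with equal group sizes
the two produce identical search trajectories, which is tested.  With the
Pareto diversity slot holding the configured criterion, k-means and k-plus
balancing are obtained by supplying squared Euclidean distances on raw or
augmented features.

## Randomness and reproducibility

Every stochastic component — initial partitions, certificate completions,
weight draws, perturbations, the greedy coloring pass — consumes R's
global random number stream, in a fixed order.  A single `set.seed()`
therefore reproduces complete runs bit for bit, which the test suite
asserts.  Dominance comparisons use exact floating-point inequalities on
stored scores; criterion equalities in tests use a relative tolerance of
$10^{-9}$; distance values are compared exactly as stored during the
threshold sweep, with tied values processed as one step — users with noisy
matrices should round them deliberately rather than rely on epsilon
merging.

## The synthetic benchmark

`generate_dataset()` draws i.i.d. normal features (mean 0, common standard
deviation, zero population correlation).  `run_benchmark()` follows a
fixed design: for each $K \in \{2,3,4,5\}$, the sample size is uniform
over the multiples of $K$ in $[20, 120]$, the feature count uniform on
$\{2,\dots,5\}$, and the standard deviation uniform on $\{1,2,3\}$ — where
the design leaves a sampling law unstated (the law for $N$, $P$, $\sigma$),
uniform over the feasible values is adopted once.  Squared Euclidean
distances feed both criteria by default (the distance choice is exposed).
Each dataset is labeled by *restriction level*: among 100 random
certificate completions, no duplicates means the dispersion constraint
barely restricts the search (`"none"`), all identical means it fixes the
partition (`"maximum"`).  Six methods are compared — restricted LCW with
one and with many initializations, and the four hybrid BILS variants
(hybrid-1/hybrid-all, with and without the ILS phase) — each with 100
restarts, each scored by the diversity of its maximum-dispersion Pareto
entry and flagged "good" when within 0.1% of the best diversity attained
on that dataset.  A dataset whose dispersion solve exhausts the node
budget is replaced and counted in the `skipped` attribute.

The default scales — 200 benchmark datasets, 500 oracle instances at
$N \le 10$, 150 maximum-restriction instances at $K = 5$ — are the
package's chosen test sizes: large enough for the binomial error on a
proportion to sit in the low percentage points, small enough to run
routinely.

What the generator does *not* emulate: correlated or heavy-tailed
features, categorical variables (users pre-code them numerically, e.g.
binary room type in a stimulus pool), missing data, and dissimilarities
that are not metric transforms of features (except the bundled normalized
Levenshtein distance for word lists).  Passing benchmarks on this design
therefore demonstrates algorithmic correctness and relative method
quality under clean conditions, not performance claims for arbitrary real
data.

## Known limitations

* All exact components face NP-hard worst cases; the node budgets convert
  them into clean `antipart_solver_limit` errors rather than wrong answers
  or silent stalls.  The exact diversity maximizer is practical only for
  small instances (roughly $N \le 20$ raw; the adjusted sweeps used by the
  frontier computation are run at $N \le 10$ in the tests).
* The dispersion of an all-singleton partition is reported as `Inf` (a
  vacuous minimum), chosen over an error so Pareto bookkeeping degrades
  gracefully; the boundary weights of the weighted score are evaluated as
  pure criteria so the sentinel never produces `NaN`.
* `partition_count()` returns a digit string because the counts overflow
  doubles already at moderate $N$; the arithmetic is exact.
* Pareto sets are exact with respect to the partitions *visited*; only the
  exact constraint method guarantees frontier optimality.
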