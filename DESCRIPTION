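Package: antipart
Title: Bicriterion Anticlustering with Exact Maximum Dispersion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Partitions a set of objects into groups that are similar to each
    other at the group level while being maximally heterogeneous within
    groups (anticlustering). Provides the within-group sum of dissimilarities
    (diversity), its size-normalized variant, the k-means and k-plus
    criteria, and the worst-case within-group dissimilarity (dispersion).
    Includes an exact maximum-dispersion solver based on a threshold sweep
    with cardinality-bounded graph coloring, an exact bicriterion constraint
    method that maximizes diversity while preserving optimal dispersion,
    generation of exact Pareto sets, and hybrid multistart/iterated local
    search heuristics with Pareto bookkeeping. Supports distinct
    dissimilarity matrices for the two criteria, normalized Levenshtein
    distances for word stimuli, general cannot-link constraints, and a
    simulation harness for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
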