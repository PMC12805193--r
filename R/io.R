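# Readers and writers for the plain-text interchange formats: feature
# tables and dissimilarity matrices (CSV/TSV), partitions (two-column TSV),
# and Pareto summaries (JSON).

sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a feature table
#'
#' CSV or TSV with a header row; the delimiter is sniffed from the first
#' line unless given.  With `id_col = TRUE` the first column supplies object
#' identifiers (kept as row names); identifiers must be unique.  Any
#' non-numeric or missing cell is reported with its row and column.
#'
#' @param path file path.
#' @param id_col does the first column hold object IDs?
#' @param sep field separator; `NULL` to sniff.
#' @return numeric matrix with object IDs as row names.
#' @export
read_feature_table <- function(path, id_col = FALSE, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (id_col) {
    ids <- df[[1L]]
    if (anyDuplicated(ids)) stop("duplicate object IDs in ", path)
    df <- df[, -1L, drop = FALSE]
  } else {
    ids <- as.character(seq_len(nrow(df)))
  }
  X <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(ids, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   df[[j]][bad[1L]], bad[1L], names(df)[j]))
    X[, j] <- v
  }
  check_features(X)
  X
}

#' Read a dissimilarity matrix
#'
#' Square numeric CSV/TSV, with or without a header row and leading ID
#' column (detected from the file).  Symmetry is validated to a tolerance
#' of 1e-8 and the matrix is then symmetrized by averaging; the diagonal is
#' forced to zero.  Negative off-diagonal entries are rejected.
#'
#' @inheritParams read_feature_table
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  has_header <- anyNA(suppressWarnings(as.numeric(unlist(raw[1L, ]))))
  first_col <- if (has_header) raw[[1L]][-1L] else raw[[1L]]
  has_ids <- anyNA(suppressWarnings(as.numeric(first_col)))
  ids <- NULL
  if (has_header) {
    ids <- as.character(unlist(raw[1L, ]))
    if (has_ids) ids <- ids[-1L]
    raw <- raw[-1L, , drop = FALSE]
  }
  if (has_ids) {
    if (is.null(ids)) ids <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  }
  D <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow(raw)))
  if (anyNA(D)) stop("non-numeric entries in distance matrix ", path)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8)
    stop("distance matrix is asymmetric beyond tolerance 1e-8")
  D <- (D + t(D)) / 2
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix diagonal must be zero")
  diag(D) <- 0
  if (any(D < 0)) stop("raw distance matrices must be nonnegative")
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  D
}

#' Write a partition as a two-column TSV
#'
#' Columns `object_id` and `cluster` (1-based).
#'
#' @param clusters integer partition.
#' @param path output path.
#' @param ids object identifiers (default 1..N).
#' @export
write_partition <- function(clusters, path, ids = NULL) {
  ids <- ids %||% as.character(seq_along(clusters))
  utils::write.table(data.frame(object_id = ids,
                                cluster = as.integer(clusters)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition written by [write_partition()]
#'
#' @param path input path.
#' @return integer partition (object order as in the file), with object IDs
#'   as names.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  setNames(as.integer(df$cluster), as.character(df$object_id))
}

#' Write a Pareto set and run metadata to a directory
#'
#' Writes one partition TSV per entry, a `pareto.json` summary (entries
#' sorted by descending dispersion, numbers at full precision) and a
#' `run.json` log with the seed and configuration echo.
#'
#' @param S a nonempty [pareto_set()].
#' @param dir output directory (created if missing).
#' @param ids object identifiers.
#' @param config optional list echoed into the run log.
#' @param seed optional seed recorded in the run log.
#' @return the paths written, invisibly.
#' @export
write_results <- function(S, dir, ids = NULL, config = NULL, seed = NULL) {
  stopifnot(inherits(S, "pareto_set"))
  if (length(S$entries) == 0L)
    stop_classed("antipart_internal", "refusing to write an empty Pareto set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- vapply(S$entries, `[[`, numeric(1), "dispersion")
  ord <- order(-ds)
  files <- character(length(ord))
  summary <- vector("list", length(ord))
  for (t in seq_along(ord)) {
    e <- S$entries[[ord[t]]]
    files[t] <- file.path(dir, sprintf("partition_%03d.tsv", t))
    write_partition(e$partition, files[t], ids)
    summary[[t]] <- list(diversity = e$diversity, dispersion = e$dispersion,
                         partition_file = basename(files[t]))
  }
  pareto_path <- file.path(dir, "pareto.json")
  jsonlite::write_json(summary, pareto_path, auto_unbox = TRUE, digits = NA)
  run_path <- file.path(dir, "run.json")
  jsonlite::write_json(list(seed = seed, config = config,
                            n_entries = length(ord)),
                       run_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, pareto_path, run_path))
}
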