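#' Modularity score of a feature subset
#'
#' The subset-quality criterion at the heart of k-FSGFS: the Newman-Girvan
#' modularity Q of the K-nearest-neighbor sample graph built in the given
#' feature subset, evaluated under the class-label partition.
#'
#' @param ds a [labeled_dataset()].
#' @param subset non-empty integer vector of feature indices (1-based).
#' @param K neighbor count for [build_ksg()]; the default 2 is the value
#'   used throughout the worked examples.
#' @param ties tie rule, see [build_ksg()].
#' @return Modularity Q of the subset's sample graph.
#' @export
score_subset <- function(ds, subset, K = 2L, ties = c("all", "first")) {
  ties <- match.arg(ties)
  g <- build_ksg(ds, subset, K, ties)
  modularity_community(g, ds$labels)$Q
}

#' Greedy forward feature selection by sample-graph modularity (k-FSGFS)
#'
#' Grows a feature subset S one feature at a time. Step 1 scans every
#' single feature and keeps the one whose 1-feature sample graph has the
#' largest modularity Q under the class partition; each later step adds the
#' candidate f maximizing Q of the graph in `S u {f}`. The search is pure
#' forward (no removals) and stops when `|S| = P`. Candidates are scanned
#' in ascending index and exact score ties are broken by the lowest feature
#' index, so the trace is deterministic.
#'
#' @param ds a [labeled_dataset()].
#' @param P number of features to select, `1 <= P <= n_features(ds)`.
#' @param K neighbor count for the sample graphs.
#' @param ties tie rule, see [build_ksg()].
#' @param log_candidates if TRUE, record the Q of every candidate at every
#'   step in `candidate_log`.
#' @return An object of class `selection_trace`: list with `selected`
#'   (feature indices in selection order), `q_values` (Q after each step),
#'   `feature_names`, `K`, `P`, `ties` and optionally `candidate_log` (one
#'   named numeric vector per step).
#' @export
kfsgfs_select <- function(ds, P, K = 2L, ties = c("all", "first"),
                          log_candidates = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  ties <- match.arg(ties)
  n <- n_features(ds)
  P <- as.integer(P)
  if (P < 1L) stop("P must be positive")
  if (P > n) stop("P must be at most the number of features")

  selected <- integer(0)
  q_values <- numeric(0)
  candidate_log <- if (log_candidates) vector("list", P) else NULL
  for (step in seq_len(P)) {
    candidates <- setdiff(seq_len(n), selected)
    scores <- vapply(candidates, function(f)
      score_subset(ds, c(selected, f), K, ties), numeric(1))
    best <- candidates[which.max(scores)]  # ties -> lowest index (ascending scan)
    selected <- c(selected, best)
    q_values <- c(q_values, max(scores))
    if (log_candidates)
      candidate_log[[step]] <- stats::setNames(scores, ds$feature_names[candidates])
  }
  structure(
    list(selected = selected, q_values = q_values,
         feature_names = ds$feature_names[selected],
         K = K, P = P, ties = ties, candidate_log = candidate_log),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("k-FSGFS selection trace (P = %d, K = %d):\n", x$P, x$K))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.selection_trace <- function(x, ...) {
  data.frame(rank = seq_along(x$selected), feature = x$selected,
             name = x$feature_names, Q = x$q_values)
}

#' Serialize a selection trace
#'
#' @param x a `selection_trace`.
#' @param path output file; `.json` or `.tsv` (rank and feature name).
#' @export
write_trace <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(selected = x$selected, q_values = x$q_values,
           feature_names = x$feature_names, K = x$K, P = x$P, ties = x$ties),
      path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.table(
      data.frame(rank = seq_along(x$selected), name = x$feature_names),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
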