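#' Build the k-features sample graph (k-FSG)
#'
#' Constructs a binary, symmetric K-nearest-neighbor graph over the samples
#' of a dataset, with distances measured by the Euclidean metric restricted
#' to a chosen feature subset. An undirected edge joins samples i and j when
#' either is among the other's K nearest neighbors (OR symmetrization); a
#' sample is never its own neighbor.
#'
#' Distance ties at the K-th rank are resolved by the `ties` rule:
#' \describe{
#'   \item{`"all"` (default)}{every neighbor tied with the K-th nearest is
#'     admitted, so the neighborhood can exceed K. This rule is invariant
#'     to the order in which samples are stored, which matters for
#'     low-precision or discretized measurements where exact distance ties
#'     are common.}
#'   \item{`"first"`}{exactly K neighbors, ties broken by ascending sample
#'     index. Deterministic, but the graph then depends on sample order
#'     whenever ties occur.}
#' }
#'
#' @param ds a [labeled_dataset()] or a numeric matrix of samples.
#' @param feature_subset integer vector of column indices (1-based) to
#'   restrict the metric to.
#' @param K neighbor count, `1 <= K <= m - 1` where m is the sample count.
#' @param ties tie rule at the K-th neighbor rank, see Details.
#' @return An object of class `sample_graph`: list with `adjacency`
#'   (m x m binary symmetric integer matrix, zero diagonal), `K`,
#'   `feature_subset`, `edge_count` (undirected edges), `degrees`, `ties`.
#' @export
build_ksg <- function(ds, feature_subset, K, ties = c("all", "first")) {
  ties <- match.arg(ties)
  values <- if (inherits(ds, "labeled_dataset")) ds$values else as.matrix(ds)
  m <- nrow(values)
  feature_subset <- as.integer(feature_subset)
  if (length(feature_subset) == 0L) stop("feature subset must be non-empty")
  if (any(feature_subset < 1L) || any(feature_subset > ncol(values)))
    stop("feature subset indices out of range")
  K <- as.integer(K)
  if (K < 1L) stop("K must be positive")
  if (K >= m) stop("K must be at most m - 1")

  D <- as.matrix(stats::dist(values[, feature_subset, drop = FALSE]))
  diag(D) <- Inf
  A <- matrix(0L, m, m)
  if (ties == "first") {
    for (i in seq_len(m)) {
      nn <- order(D[i, ], seq_len(m))[seq_len(K)]
      A[i, nn] <- 1L
    }
  } else {
    for (i in seq_len(m)) {
      dk <- sort.int(D[i, ], partial = K)[K]
      A[i, D[i, ] <= dk] <- 1L
    }
  }
  diag(A) <- 0L
  A <- (A | t(A)) * 1L
  storage.mode(A) <- "integer"
  degrees <- rowSums(A)
  structure(
    list(adjacency = A, K = K, feature_subset = feature_subset,
         edge_count = sum(degrees) / 2, degrees = degrees, ties = ties),
    class = "sample_graph"
  )
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("sample_graph: %d nodes, %d edges, K = %d, features {%s}, ties = %s\n",
              nrow(x$adjacency), x$edge_count, x$K,
              paste(x$feature_subset, collapse = ", "), x$ties))
  invisible(x)
}

#' Export a sample graph as an undirected edge list
#'
#' Writes one tab-separated `i j` pair per undirected edge (1-based sample
#' indices, i < j), for inspection with external graph tools.
#'
#' @param g a `sample_graph`.
#' @param path output file.
#' @export
export_edgelist <- function(g, path) {
  idx <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  utils::write.table(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE],
                     path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
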