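#' Class-label partition of a sample graph
#'
#' The partition used throughout this package assigns every sample to the
#' community given by its class label, so a high modularity Q means
#' same-class samples are densely interconnected and different classes are
#' sparsely connected.
#'
#' @param ds a [labeled_dataset()], or an integer membership vector with
#'   codes `0 .. n_c - 1`.
#' @return Integer membership vector (codes `0 .. n_c - 1`).
#' @export
class_partition <- function(ds) {
  membership <- if (inherits(ds, "labeled_dataset")) ds$labels else as.integer(ds)
  codes <- sort(unique(membership))
  if (!identical(codes, 0:(length(codes) - 1L)))
    stop("community codes must be exactly 0 .. n_c - 1")
  membership
}

check_partition <- function(g, membership) {
  membership <- class_partition(membership)
  if (length(membership) != nrow(g$adjacency))
    stop("partition length must match node count")
  if (g$edge_count == 0) stop("modularity undefined for an edgeless graph")
  membership
}

#' Newman-Girvan modularity, pairwise form
#'
#' Evaluates
#' \deqn{Q = \frac{1}{2e} \sum_{i,j} \left[A_{ij} - \frac{d_i d_j}{2e}\right]
#'       \delta(c_i, c_j)}
#' where the sum runs over all ordered pairs of nodes (the diagonal
#' contributes only its null-model term, since `A(i,i) = 0`), `e` is the
#' number of undirected edges, `d_i` the node degrees and `delta` indicates
#' co-membership. The prefactor `1/(2e)` makes this form agree exactly with
#' the community-sum form of [modularity_community()].
#'
#' @param g a [build_ksg()] sample graph (or any `sample_graph`).
#' @param membership community assignment: a `labeled_dataset`, or an
#'   integer vector of codes `0 .. n_c - 1`.
#' @return Modularity Q, a real number in \[-1, 1\].
#' @export
modularity_pairwise <- function(g, membership) {
  membership <- check_partition(g, membership)
  A <- g$adjacency
  d <- g$degrees
  two_e <- 2 * g$edge_count
  same <- outer(membership, membership, "==")
  sum((A - outer(d, d) / two_e) * same) / two_e
}

#' Newman-Girvan modularity, community-sum form
#'
#' Evaluates
#' \deqn{Q = \sum_c \left[\frac{l_c}{e} - \left(\frac{d_c}{2e}\right)^2\right]}
#' where `l_c` is the number of edges joining nodes of community c and
#' `d_c` the sum of their degrees. Algebraically identical to
#' [modularity_pairwise()]; both are computed so each can check the other.
#'
#' @inheritParams modularity_pairwise
#' @return An object of class `modularity_report`: list with `Q`,
#'   per-community `l_c` and `d_c`, `e`, and `n_communities`.
#' @export
modularity_community <- function(g, membership) {
  membership <- check_partition(g, membership)
  A <- g$adjacency
  e <- g$edge_count
  codes <- sort(unique(membership))
  l_c <- d_c <- stats::setNames(numeric(length(codes)), codes)
  for (k in seq_along(codes)) {
    in_c <- membership == codes[k]
    l_c[k] <- sum(A[in_c, in_c, drop = FALSE]) / 2
    d_c[k] <- sum(g$degrees[in_c])
  }
  structure(
    list(Q = sum(l_c / e - (d_c / (2 * e))^2),
         l_c = l_c, d_c = d_c, e = e, n_communities = length(codes)),
    class = "modularity_report"
  )
}

#' @export
print.modularity_report <- function(x, ...) {
  cat(sprintf("modularity report: Q = %.4f over %d communities (e = %d)\n",
              x$Q, x$n_communities, x$e))
  df <- data.frame(community = names(x$l_c), l_c = x$l_c, d_c = x$d_c,
                   row.names = NULL)
  print(df)
  invisible(x)
}
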