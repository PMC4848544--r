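#' Expected number of correctly classified samples (ENC)
#'
#' Neighborhood-components-style justification of the modularity criterion:
#' in the chosen feature subset, each sample i picks another sample j as
#' its neighbor with softmax probability
#' \deqn{P_{ij} = \frac{\exp(-\|x_i - x_j\|^2)}{\sum_{j' \ne i}
#'       \exp(-\|x_i - x_{j'}\|^2)},}
#' and is correctly classified with probability
#' `P_i = sum of P_ij over same-class j`. ENC is the sum of the `P_i`;
#' ENIC = m - ENC. A feature subset in which same-class samples are mutual
#' near neighbors (hence a high-Q sample graph) yields a large ENC.
#'
#' Exponents are shifted by the per-row maximum before exponentiation
#' (log-sum-exp stabilization), so microarray-scale distances do not
#' underflow. The exponent uses the squared Euclidean distance by default;
#' `distance = "plain"` uses the unsquared distance.
#'
#' @param ds a [labeled_dataset()], or a bare numeric matrix (in which case
#'   `labels` must be given -- unlike a full dataset, the diagnostic is well
#'   defined even when every sample shares one class).
#' @param subset non-empty integer vector of feature indices.
#' @param distance `"squared"` (default) or `"plain"` in the exponent.
#' @param labels integer class codes when `ds` is a matrix.
#' @return An object of class `nca_matrix`: list with `P` (m x m
#'   row-stochastic matrix, zero diagonal), `p_correct` (per-sample `P_i`),
#'   `ENC`, `ENIC` and `m`.
#' @export
expected_correct_count <- function(ds, subset, distance = c("squared", "plain"),
                                   labels = NULL) {
  distance <- match.arg(distance)
  if (inherits(ds, "labeled_dataset")) {
    values <- ds$values
    labels <- ds$labels
  } else {
    values <- as.matrix(ds)
    if (is.null(labels)) stop("labels are required for a bare matrix")
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
      stop("one label per row is required")
  }
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("feature subset must be non-empty")
  m <- nrow(values)
  if (m < 2L) stop("at least 2 samples are required")

  D <- as.matrix(stats::dist(values[, subset, drop = FALSE]))
  expo <- if (distance == "squared") -D^2 else -D
  diag(expo) <- -Inf
  shift <- apply(expo, 1L, max)
  W <- exp(expo - shift)
  diag(W) <- 0
  P <- W / rowSums(W)
  same <- outer(labels, labels, "==")
  p_correct <- rowSums(P * same)
  ENC <- sum(p_correct)
  structure(
    list(P = P, p_correct = p_correct, ENC = ENC, ENIC = m - ENC, m = m,
         distance = distance),
    class = "nca_matrix"
  )
}

#' @export
print.nca_matrix <- function(x, ...) {
  cat(sprintf("softmax neighbor model: m = %d, ENC = %.3f, ENIC = %.3f\n",
              x$m, x$ENC, x$ENIC))
  invisible(x)
}

#' K-means clustering objective (evaluation only)
#'
#' Evaluates the total distance of each point to its assigned cluster
#' center,
#' \deqn{J = \sum_i \|x_i - \mu_{a(i)}\|^2}
#' (squared Euclidean by default; `distance = "plain"` sums unsquared
#' distances). No iterations are performed: the function scores a given
#' assignment, serving as the clustering-side counterpart of ENC -- feature
#' subsets with high modularity Q concentrate same-class samples around
#' their centers and so attain a small J.
#'
#' @param points numeric matrix, one row per point.
#' @param centers numeric matrix of cluster centers, same column count.
#' @param assignment integer vector of center indices (1-based), one per
#'   point.
#' @param distance `"squared"` (default) or `"plain"`.
#' @return An object of class `kmeans_objective`: list with `J`, `centers`,
#'   `assignment` and `n_clusters`.
#' @export
kmeans_objective <- function(points, centers, assignment,
                             distance = c("squared", "plain")) {
  distance <- match.arg(distance)
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  assignment <- as.integer(assignment)
  if (ncol(points) != ncol(centers)) stop("dimension mismatch")
  if (length(assignment) != nrow(points))
    stop("one assignment per point is required")
  if (any(assignment < 1L) || any(assignment > nrow(centers)))
    stop("assignment indices out of range")
  diffs <- points - centers[assignment, , drop = FALSE]
  sq <- rowSums(diffs^2)
  J <- if (distance == "squared") sum(sq) else sum(sqrt(sq))
  structure(
    list(J = J, centers = centers, assignment = assignment,
         n_clusters = nrow(centers), distance = distance),
    class = "kmeans_objective"
  )
}

#' @export
print.kmeans_objective <- function(x, ...) {
  cat(sprintf("k-means objective: J = %.4f over %d cluster(s)\n",
              x$J, x$n_clusters))
  invisible(x)
}
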