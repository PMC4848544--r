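# Independent oracles and fixtures used across the suite. These are written
# as naive enumerations on purpose: they must not share code paths with the
# package implementation they check.

# brute-force KNN edge enumeration: for each node, rank all others by
# distance (ties by ascending index), take the first K, then OR-symmetrize
oracle_knn_edges <- function(X, K) {
  X <- as.matrix(X)
  m <- nrow(X)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(m)) {
    d <- numeric(m)
    for (j in seq_len(m)) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    ord <- setdiff(order(d, seq_len(m)), i)
    for (j in ord[seq_len(K)]) {
      edges <- rbind(edges, sort(c(i, j)))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edge_set <- function(g) {
  idx <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- NULL
  idx
}

# wrap a bare adjacency matrix as the graph object the modularity code
# expects, so hand-built graphs can be scored
graph_from_adjacency <- function(A) {
  A <- (A | t(A)) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  structure(list(adjacency = A, K = NA_integer_,
                 feature_subset = NA_integer_,
                 edge_count = sum(A) / 2, degrees = rowSums(A),
                 ties = "all"),
            class = "sample_graph")
}

# two 3-cliques joined by one bridge edge; nodes 1:3 and 4:6
clique_bridge_graph <- function() {
  A <- matrix(0L, 6, 6)
  for (pair in list(c(1,2), c(1,3), c(2,3), c(4,5), c(4,6), c(5,6), c(3,4)))
    A[pair[1], pair[2]] <- A[pair[2], pair[1]] <- 1L
  graph_from_adjacency(A)
}

# explicit double sum over all ordered node pairs
oracle_modularity_pairs <- function(A, membership) {
  d <- rowSums(A)
  e <- sum(A) / 2
  s <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(A))) {
      if (membership[i] == membership[j])
        s <- s + A[i, j] - d[i] * d[j] / (2 * e)
    }
  }
  s / (2 * e)
}

# sparse random symmetric graph plus a random partition, for the
# two-forms-agree property
random_graph_case <- function(m = 12, p = 0.3, n_comm = 3) {
  repeat {
    A <- matrix(0L, m, m)
    A[upper.tri(A)] <- stats::rbinom(m * (m - 1) / 2, 1, p)
    A <- A + t(A)
    if (sum(A) > 0) break
  }
  list(g = graph_from_adjacency(A),
       membership = sample(0:(n_comm - 1), m, replace = TRUE) |>
         (\(v) match(v, sort(unique(v))) - 1L)())
}

# entropy-decomposition CMI oracle: I(X;C|Z) = H(X,Z) + H(C,Z) - H(X,C,Z) - H(Z)
oracle_entropy <- function(..., base = 2) {
  p <- as.numeric(table(...)) / length(..1)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}
oracle_cmi <- function(x, c, z, base = 2) {
  oracle_entropy(x, z, base = base) + oracle_entropy(c, z, base = base) -
    oracle_entropy(x, c, z, base = base) - oracle_entropy(z, base = base)
}

# direct softmax evaluation with explicit exp terms (no stabilization)
oracle_enc <- function(X, labels) {
  X <- as.matrix(X)
  m <- nrow(X)
  total <- 0
  for (i in seq_len(m)) {
    w <- numeric(m)
    for (j in seq_len(m)) if (j != i) w[j] <- exp(-sum((X[i, ] - X[j, ])^2))
    p <- w / sum(w)
    total <- total + sum(p[which(labels == labels[i] & seq_len(m) != i)])
  }
  total
}

iris_ds <- function() {
  labeled_dataset(as.matrix(iris[, 1:4]), as.integer(iris$Species) - 1L,
                  feature_names = colnames(iris)[1:4],
                  class_names = levels(iris$Species))
}

# two tight, well-separated Gaussian blobs
blob_ds <- function(n_per = 50, sd = 0.01, sep = 10, seed = 42) {
  set.seed(seed)
  x <- c(stats::rnorm(n_per, -sep, sd), stats::rnorm(n_per, sep, sd))
  y <- c(stats::rnorm(n_per, -sep, sd), stats::rnorm(n_per, sep, sd))
  labeled_dataset(cbind(x, y), rep(0:1, each = n_per))
}

tiny_ds <- function(values, labels) labeled_dataset(as.matrix(values), labels)
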