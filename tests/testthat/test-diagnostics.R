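test_that("two-sample softmax neighbor model is deterministic", {
  # same class: each sample must pick the other, so both classify correctly
  nca_same <- expected_correct_count(cbind(c(0, 3)), 1, labels = c(0, 0))
  expect_equal(nca_same$ENC, 2)
  expect_equal(unname(nca_same$P[1, 2]), 1)
  expect_equal(unname(nca_same$P[2, 1]), 1)
  # different classes: the only available neighbor is wrong
  nca_diff <- expected_correct_count(tiny_ds(cbind(c(0, 3)), c(0, 1)), 1)
  expect_equal(nca_diff$ENC, 0)
  expect_equal(nca_diff$ENIC, 2)
})

test_that("three-point ENC matches brute-force softmax evaluation", {
  ds <- tiny_ds(cbind(c(0, 1, 5)), c(0, 0, 1))
  nca <- expected_correct_count(ds, 1)
  expect_equal(nca$ENC, oracle_enc(ds$values, ds$labels), tolerance = 1e-12)
  # hand evaluation: P_12 = e^-1 / (e^-1 + e^-25), symmetric for point 2
  p12 <- exp(-1) / (exp(-1) + exp(-25))
  p21 <- exp(-1) / (exp(-1) + exp(-16))
  expect_equal(nca$ENC, p12 + p21, tolerance = 1e-12)
})

test_that("rows are stochastic and ENC + ENIC = m exactly", {
  set.seed(6)
  for (i in 1:5) {
    ds <- labeled_dataset(matrix(rnorm(40 * 3), 40, 3),
                          sample(0:2, 40, replace = TRUE) |>
                            (\(v) match(v, sort(unique(v))) - 1L)())
    nca <- expected_correct_count(ds, 1:3)
    expect_equal(unname(rowSums(nca$P)), rep(1, 40), tolerance = 1e-12)
    expect_true(all(diag(nca$P) == 0))
    expect_true(all(nca$p_correct >= 0 & nca$p_correct <= 1))
    expect_equal(nca$ENC + nca$ENIC, 40)
  }
})

test_that("ENC is invariant to translation and sample permutation", {
  set.seed(12)
  ds <- labeled_dataset(matrix(rnorm(30 * 2), 30, 2), rep(0:1, 15))
  enc0 <- expected_correct_count(ds, 1:2)$ENC
  shifted <- labeled_dataset(ds$values + 100, ds$labels)
  expect_equal(expected_correct_count(shifted, 1:2)$ENC, enc0,
               tolerance = 1e-9)
  perm <- sample(30)
  permuted <- labeled_dataset(ds$values[perm, ], ds$labels[perm])
  expect_equal(expected_correct_count(permuted, 1:2)$ENC, enc0,
               tolerance = 1e-9)
})

test_that("the stabilized softmax survives microarray-scale distances", {
  ds <- labeled_dataset(cbind(c(0, 1e4, 2e4, 2e4 + 1)), c(0, 0, 1, 1))
  nca <- expected_correct_count(ds, 1)
  expect_false(anyNA(nca$P))
  expect_equal(unname(rowSums(nca$P)), rep(1, 4), tolerance = 1e-12)
})

test_that("single-feature Q and ENC rank features concordantly", {
  # informative features should score high and noise low on both criteria;
  # this is the clustering-side justification of the modularity score
  rhos <- vapply(1:20, function(seed) {
    ds <- standardize(generate_synthetic(synthetic_spec(
      samples_per_class = 75, seed = seed)))
    n <- n_features(ds)
    q1 <- vapply(seq_len(n), function(f) score_subset(ds, f, K = 2), numeric(1))
    e1 <- vapply(seq_len(n), function(f)
      expected_correct_count(ds, f)$ENC, numeric(1))
    stats::cor(q1, e1, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0))
})

test_that("k-means objective evaluates assignments without iterating", {
  pts <- rbind(c(0, 0), c(2, 0))
  expect_equal(kmeans_objective(pts, pts, c(1, 2))$J, 0)
  obj <- kmeans_objective(pts, rbind(c(1, 0)), c(1, 1))
  expect_equal(obj$J, 2)  # (0-1)^2 + (2-1)^2
  expect_equal(kmeans_objective(pts, rbind(c(1, 0)), c(1, 1),
                                distance = "plain")$J, 2)
  # appending a point exactly at a center leaves J unchanged
  obj2 <- kmeans_objective(rbind(pts, c(1, 0)), rbind(c(1, 0)), c(1, 1, 1))
  expect_equal(obj2$J, obj$J)
  expect_error(kmeans_objective(pts, rbind(c(1, 0, 0)), c(1, 1)),
               "dimension mismatch")
  expect_error(kmeans_objective(pts, rbind(c(1, 0)), c(1, 2)),
               "out of range")
})

test_that("diagnostics argument validation", {
  ds <- tiny_ds(cbind(c(0, 1)), c(0, 1))
  expect_error(expected_correct_count(ds, integer(0)), "non-empty")
  expect_error(expected_correct_count(cbind(1), 1, labels = 0L),
               "at least 2 samples")
  expect_error(expected_correct_count(cbind(c(1, 2)), 1), "labels")
})
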