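test_that("svmlight parsing densifies sparse rows and recodes labels", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 1:0.5 3:-1.0", "2 2:2.0"), f)
  ds <- load_dataset(f, "svmlight")
  expect_equal(ds$values, matrix(c(0.5, 0, 0, 2, -1, 0), 2, 3,
                                 dimnames = list(NULL, paste0("f", 1:3))))
  expect_equal(ds$labels, c(0L, 1L))
  expect_equal(ds$class_names, c("1", "2"))
})

test_that("empty or malformed inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  expect_error(load_dataset(f, "svmlight"), "zero samples")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,x,yes", "2,3,no"), g)
  expect_error(load_dataset(g, "csv", "label"), "non-numeric")
  expect_error(load_dataset(g, "csv", "missing"), "label column")
  expect_error(load_dataset("no/such/file.csv", "csv"), "cannot read")
})

test_that("csv write -> load round trip preserves values and labels", {
  set.seed(7)
  ds <- labeled_dataset(matrix(rnorm(60), 15, 4), rep(0:2, 5),
                        class_names = c("low", "mid", "high"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- load_dataset(f, "csv", "label")
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$class_names, ds$class_names)
})

test_that("standardize centers and scales by the population sd", {
  ds <- tiny_ds(cbind(c(0, 2), c(5, 5 + 1e-16)), c(0, 1))
  expect_warning(out <- standardize(ds), "zero-variance")
  expect_equal(out$values[, 1], c(-1, 1))
  expect_equal(out$values[, 2], c(0, 0))

  set.seed(11)
  ds2 <- labeled_dataset(matrix(rnorm(250, 3, 2), 50, 5), rep(0:1, 25))
  std <- standardize(ds2)
  expect_true(all(abs(colMeans(std$values)) < 1e-10))
  expect_true(all(abs(colMeans(std$values^2) - 1) < 1e-10))
  # idempotence
  expect_equal(standardize(std)$values, std$values, tolerance = 1e-12)
})

test_that("nine-level discretization maps bands to -4..4", {
  set.seed(3)
  x <- rnorm(200, 10, 4)
  ds <- labeled_dataset(cbind(x, rnorm(200)), rep(0:1, 100))
  out <- discretize_nine_level(ds)
  mu <- unname(out$model$mu[1]); s <- unname(out$model$sigma[1])
  probe <- cbind(c(mu, mu + 0.75 * s, mu + 10 * s, mu - 10 * s,
                   mu + 0.5 * s, mu + 1.5 * s, mu - 0.6 * s),
                 rep(0, 7))
  lev <- discretize_values(out$model, probe)[, 1]
  expect_identical(lev, c(0L, 1L, 4L, -4L, 0L, 1L, -1L))
  # alphabet and monotonicity in the raw value
  d <- out$dataset$values[, 1]
  expect_true(all(d %in% -4:4))
  ord <- order(x)
  expect_true(all(diff(d[ord]) >= 0))
})

test_that("synthetic generation is deterministic under its seed", {
  spec <- synthetic_spec(seed = 99)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
  expect_identical(feature_roles(a),
                   stats::setNames(c("group", "group", rep("informative", 3),
                                     rep("redundant", 2), rep("noise", 3)),
                                   a$feature_names))
})

test_that("XOR pair members are individually silent but jointly informative", {
  spec <- synthetic_spec(samples_per_class = 200, n_classes = 2,
                         n_group_pairs = 1, n_informative = 0,
                         n_redundant = 0, n_noise = 8, seed = 5)
  ds <- generate_synthetic(spec)
  d9 <- discretize_nine_level(ds)$dataset
  mi1 <- conditional_mi(d9$values[, 1], d9$labels)$value
  mi2 <- conditional_mi(d9$values[, 2], d9$labels)$value
  joint <- interaction(d9$values[, 1], d9$values[, 2], drop = TRUE)
  mi_joint <- conditional_mi(as.integer(joint), d9$labels)$value
  expect_lt(mi1, 0.05)
  expect_lt(mi2, 0.05)
  expect_gt(mi_joint, 0.5)
})

test_that("a pure-noise feature scores within its label-permutation null", {
  spec <- synthetic_spec(samples_per_class = 150, n_classes = 2,
                         n_group_pairs = 0, n_informative = 1,
                         n_redundant = 0, n_noise = 1, seed = 8)
  ds <- generate_synthetic(spec)
  noise_col <- which(feature_roles(ds) == "noise")
  g <- build_ksg(ds, noise_col, K = 2)
  q_obs <- modularity_community(g, ds$labels)$Q
  set.seed(1)
  q_null <- replicate(199, modularity_community(g, sample(ds$labels))$Q)
  expect_lt(q_obs, stats::quantile(q_null, 0.95))
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec(n_classes = 1), "class count")
  expect_error(synthetic_spec(n_group_pairs = 0, n_informative = 0,
                              n_redundant = 0, n_noise = 0), "total features")
  expect_error(synthetic_spec(n_informative = 0, n_redundant = 2,
                              n_group_pairs = 1), "redundant")
})
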