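# 1NN with Euclidean distance over given columns; distance ties go to the
# lowest training index (which.min is exactly that rule).
predict_1nn <- function(train_x, train_y, test_x) {
  apply(test_x, 1L, function(q) {
    d2 <- colSums((t(train_x) - q)^2)
    train_y[which.min(d2)]
  })
}

# fold ids: stratified when every class can fill each fold, otherwise plain
# random folds with a warning
make_folds <- function(labels, folds) {
  m <- length(labels)
  fold_id <- integer(m)
  class_sizes <- table(labels)
  if (all(class_sizes >= folds)) {
    for (cl in names(class_sizes)) {
      idx <- which(labels == as.integer(cl))
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    warning("a class has fewer members than folds; falling back to plain folds")
    fold_id <- sample(rep_len(seq_len(folds), m))
  }
  fold_id
}

#' 1-nearest-neighbor cross-validated accuracy
#'
#' The evaluation protocol for selected feature subsets: 1NN with Euclidean
#' distance over the subset's columns, k-fold cross-validation (stratified
#' fold assignment), repeated for several independent runs whose fold
#' assignments are re-randomized; run r uses RNG seed `seed + r`. Distance
#' ties are broken by the lowest training-sample index, so a given seed
#' reproduces the report exactly.
#'
#' @param ds a [labeled_dataset()].
#' @param subset non-empty integer vector of feature indices to classify in.
#' @param folds number of cross-validation folds (default 10).
#' @param runs number of independent repetitions averaged (default 10).
#' @param seed base RNG seed.
#' @return An object of class `cv_report`: list with `s` (subset size),
#'   `run_accuracies` (percent, one per run), `mean_accuracy` (percent,
#'   arithmetic mean of the per-run values), `fold_accuracies`
#'   (runs x folds matrix, percent), `folds`, `runs`, `seed`.
#' @export
knn1_cross_val <- function(ds, subset, folds = 10L, runs = 10L, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("feature subset must be non-empty")
  m <- n_samples(ds)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > m) stop("more folds than samples")
  X <- ds$values[, subset, drop = FALSE]
  y <- ds$labels

  fold_acc <- matrix(NA_real_, runs, folds)
  run_acc <- numeric(runs)
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    fold_id <- make_folds(y, folds)
    correct <- logical(m)
    for (k in seq_len(folds)) {
      test <- fold_id == k
      pred <- predict_1nn(X[!test, , drop = FALSE], y[!test],
                          X[test, , drop = FALSE])
      correct[test] <- pred == y[test]
      fold_acc[r, k] <- 100 * mean(pred == y[test])
    }
    run_acc[r] <- 100 * mean(correct)
  }
  structure(
    list(s = length(subset), run_accuracies = run_acc,
         mean_accuracy = mean(run_acc), fold_accuracies = fold_acc,
         folds = folds, runs = runs, seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("1NN %d-fold CV over %d run(s), s = %d features: mean accuracy %.2f%%\n",
              x$folds, x$runs, x$s, x$mean_accuracy))
  invisible(x)
}

#' Paired one-tailed t-test
#'
#' Tests whether the mean of `a` exceeds the mean of `b` on paired
#' observations (alternative: `mean(a - b) > 0`), as used to compare the
#' per-cell accuracies of two feature-selection methods across datasets and
#' subset sizes.
#'
#' @param a,b numeric vectors of equal length (>= 2), paired.
#' @return An object of class `t_test_result`: list with `statistic`, `df`
#'   (`length(a) - 1`), `p_value` (one-tailed) and `alternative`.
#' @export
paired_one_tailed_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("at least 2 pairs are required")
  d <- a - b
  if (stats::var(d) == 0)
    stop("degenerate test: differences have zero variance")
  res <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  structure(
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, alternative = "mean(a - b) > 0"),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("paired one-tailed t-test: t = %.4f, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$alternative))
  invisible(x)
}
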