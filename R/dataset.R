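#' Labeled dataset container
#'
#' Bundles a numeric sample-by-feature matrix with integer class codes and
#' bookkeeping names. This is the container every other function in the
#' package consumes: rows are samples, columns are features, and `labels`
#' holds class codes `0 .. n_classes - 1` in first-appearance order of the
#' original label tokens (kept in `class_names`).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param labels integer vector of class codes, one per row of `values`.
#'   Codes must be exactly `0 .. n_classes - 1` with every code present.
#' @param feature_names character vector of unique column identifiers;
#'   defaults to `colnames(values)` or `f1, f2, ...`.
#' @param class_names original label tokens in first-appearance order; one
#'   per class code. Defaults to the code itself.
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `values`, `labels`, `feature_names`, `class_names`.
#' @export
labeled_dataset <- function(values, labels, feature_names = NULL,
                            class_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (nrow(values) == 0L) stop("zero samples")
  if (nrow(values) != length(labels))
    stop("row count of 'values' must equal length of 'labels'")
  if (anyNA(values)) stop("missing values in feature matrix")
  if (anyNA(labels)) stop("missing class labels")
  codes <- sort(unique(labels))
  n_classes <- length(codes)
  if (n_classes < 2L) stop("at least 2 distinct classes are required")
  if (!identical(codes, 0:(n_classes - 1L)))
    stop("class codes must be exactly 0 .. n_classes - 1")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values))
    stop("one feature name per column is required")
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (is.null(class_names)) class_names <- as.character(codes)
  if (length(class_names) != n_classes)
    stop("one class name per class code is required")
  colnames(values) <- feature_names
  structure(
    list(values = values, labels = labels,
         feature_names = as.character(feature_names),
         class_names = as.character(class_names)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Number of samples / features / classes of a labeled dataset
#' @param ds a `labeled_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$values)

#' @rdname n_samples
#' @export
n_features <- function(ds) ncol(ds$values)

#' @rdname n_samples
#' @export
n_classes <- function(ds) length(ds$class_names)

# recode arbitrary label tokens to 0-based codes in first-appearance order
recode_labels <- function(tokens) {
  tokens <- as.character(tokens)
  lev <- unique(tokens)
  list(codes = match(tokens, lev) - 1L, class_names = lev)
}

#' Read a labeled dataset from disk
#'
#' Supports two plain-text dialects: delimited CSV with a header row and a
#' designated label column, and sparse SVMlight/LIBSVM text
#' (`<label> <index>:<value> ...`, 1-based feature indices). Sparse entries
#' absent from an SVMlight row are filled with 0. Label tokens are re-coded
#' to integer codes `0 .. n_classes - 1` in order of first appearance; the
#' original tokens are kept in `class_names`.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"svmlight"`.
#' @param label_column for CSV, the label column as a name or 1-based
#'   position; defaults to the last column.
#' @return A [labeled_dataset()].
#' @export
load_dataset <- function(path, dialect = c("csv", "svmlight"),
                         label_column = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (dialect == "csv") load_csv(path, label_column) else load_svmlight(path)
}

load_csv <- function(path, label_column) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("zero samples")
  if (is.null(label_column)) label_column <- ncol(df)
  if (is.character(label_column)) {
    if (!label_column %in% names(df))
      stop("csv is missing the label column '", label_column, "'")
    lab_idx <- match(label_column, names(df))
  } else {
    lab_idx <- as.integer(label_column)
    if (lab_idx < 1L || lab_idx > ncol(df))
      stop("label column position out of range")
  }
  lab <- recode_labels(df[[lab_idx]])
  feat <- df[, -lab_idx, drop = FALSE]
  mat <- suppressWarnings(vapply(feat, as.numeric, numeric(nrow(feat))))
  mat <- matrix(mat, nrow = nrow(feat),
                dimnames = list(NULL, names(feat)))
  if (anyNA(mat)) stop("non-numeric feature value in csv")
  labeled_dataset(mat, lab$codes, names(feat), lab$class_names)
}

load_svmlight <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("zero samples")
  toks <- strsplit(lines, "[[:space:]]+")
  lab_tokens <- vapply(toks, `[[`, character(1), 1L)
  entries <- lapply(toks, function(tt) {
    tt <- tt[-1L]
    if (length(tt) == 0L) return(cbind(integer(0), numeric(0)))
    parts <- strsplit(tt, ":", fixed = TRUE)
    idx <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1L)))
    val <- suppressWarnings(as.numeric(vapply(parts, function(p) p[2L], character(1))))
    if (anyNA(idx) || anyNA(val) || any(idx < 1L))
      stop("malformed svmlight entry")
    cbind(idx, val)
  })
  n_feat <- max(1L, vapply(entries, function(e) if (nrow(e)) max(e[, 1L]) else 0L, numeric(1)))
  mat <- matrix(0, nrow = length(lines), ncol = n_feat)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (nrow(e)) mat[i, e[, 1L]] <- e[, 2L]
  }
  lab <- recode_labels(lab_tokens)
  labeled_dataset(mat, lab$codes, paste0("f", seq_len(n_feat)), lab$class_names)
}

#' Write a labeled dataset as CSV
#'
#' The inverse of [load_dataset()] for the CSV dialect: feature columns plus
#' a final `label` column holding the original class tokens. A
#' load -> write -> load round trip reproduces values and labels exactly.
#'
#' @param ds a `labeled_dataset`.
#' @param path output file.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$values, check.names = FALSE)
  df$label <- ds$class_names[ds$labels + 1L]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize features to zero mean and unit variance
#'
#' Each column is centered and scaled by its population standard deviation
#' (divide-by-m). Zero-variance columns cannot be scaled; they become
#' all-zero and a warning names them. The transform is idempotent.
#'
#' @param ds a `labeled_dataset`.
#' @return A `labeled_dataset` with standardized values.
#' @export
standardize <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  mu <- colMeans(ds$values)
  sigma <- sqrt(colMeans(sweep(ds$values, 2L, mu, "-")^2))
  degenerate <- sigma == 0
  if (any(degenerate)) {
    warning("zero-variance feature(s) standardized to all-zero: ",
            paste(ds$feature_names[degenerate], collapse = ", "))
    sigma[degenerate] <- 1
  }
  vals <- sweep(sweep(ds$values, 2L, mu, "-"), 2L, sigma, "/")
  labeled_dataset(vals, ds$labels, ds$feature_names, ds$class_names)
}

#' Nine-level discretization
#'
#' Maps each continuous feature to the integer alphabet `-4 .. 4` around its
#' mean: values within half a standard deviation of the mean (the central
#' band, closed on both ends) map to 0; the four intervals of width
#' `sigma` to the right of `mu + sigma/2` map to 1..4 and their mirror
#' images to -1..-4, each interval half-open away from the center; anything
#' beyond is truncated to +/-4. The standard deviation is the population
#' form, computed from the data being discretized, so the rule is invariant
#' to prior standardization.
#'
#' @param ds a `labeled_dataset` with continuous features.
#' @return A list with `dataset` (the discretized `labeled_dataset`) and
#'   `model` (a `discretization_model` carrying per-feature `mu` and
#'   `sigma`, reusable via [discretize_values()]).
#' @export
discretize_nine_level <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  mu <- colMeans(ds$values)
  sigma <- sqrt(colMeans(sweep(ds$values, 2L, mu, "-")^2))
  if (any(sigma == 0))
    warning("zero-variance feature(s) discretize to all-zero: ",
            paste(ds$feature_names[sigma == 0], collapse = ", "))
  model <- structure(
    list(mu = stats::setNames(mu, ds$feature_names),
         sigma = stats::setNames(sigma, ds$feature_names)),
    class = "discretization_model"
  )
  vals <- discretize_values(model, ds$values)
  list(
    dataset = labeled_dataset(vals, ds$labels, ds$feature_names, ds$class_names),
    model = model
  )
}

#' Apply a fitted nine-level discretization model
#'
#' @param model a `discretization_model` from [discretize_nine_level()].
#' @param values numeric matrix (or vector for a single feature) with one
#'   column per modeled feature.
#' @return Integer matrix of levels in `-4 .. 4`.
#' @export
discretize_values <- function(model, values) {
  values <- as.matrix(values)
  if (ncol(values) != length(model$mu))
    stop("column count does not match the discretization model")
  out <- values
  for (j in seq_len(ncol(values))) {
    s <- model$sigma[j]
    if (s == 0) { out[, j] <- 0; next }
    z <- (values[, j] - model$mu[j]) / s
    a <- abs(z)
    lev <- ifelse(a <= 0.5, 0, pmin(4, ceiling(a - 0.5)))
    out[, j] <- as.vector(lev * sign(z))
  }
  storage.mode(out) <- "integer"
  out
}

#' @export
print.discretization_model <- function(x, ...) {
  cat(sprintf("nine-level discretization model for %d feature(s)\n",
              length(x$mu)))
  invisible(x)
}
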