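#' Plug-in (conditional) mutual information for discrete variables
#'
#' Maximum-likelihood estimate from the empirical joint distribution, with
#' the usual `0 log 0 = 0` convention. With `z` supplied this is the
#' conditional mutual information `I(x; c | z)`; without it, the plain
#' mutual information `I(x; c)`. Inputs must be discrete (integer-coded);
#' continuous features should first pass through [discretize_nine_level()].
#'
#' The relevant-independency diagnostic `RI(f_i, C; f_j) = I(f_i; C | f_j)`
#' measures how much a candidate feature predicts the class beyond an
#' already-selected feature; see [ri_table()].
#'
#' @param x discrete vector.
#' @param c discrete vector (the class), same length as `x`.
#' @param z optional discrete conditioning vector, same length.
#' @param base `"2"` for bits (default) or `"e"` for nats.
#' @return An object of class `cmi_estimate`: list with `value`, `base`,
#'   and the contingency `counts` used.
#' @export
conditional_mi <- function(x, c, z = NULL, base = c("2", "e")) {
  base <- match.arg(base)
  logbase <- if (base == "2") 2 else exp(1)
  n <- length(x)
  if (n == 0L) stop("empty vectors")
  if (length(c) != n || (!is.null(z) && length(z) != n))
    stop("input vectors must have equal length")
  if (is.null(z)) z <- rep(0L, n)

  counts <- table(x = x, c = c, z = z)
  p <- counts / n
  pz <- apply(p, 3L, sum)
  pxz <- apply(p, c(1L, 3L), sum)
  pcz <- apply(p, c(2L, 3L), sum)
  value <- 0
  for (k in seq_along(pz)) {
    if (pz[k] == 0) next
    for (i in seq_len(nrow(pxz))) {
      for (j in seq_len(nrow(pcz))) {
        pij <- p[i, j, k]
        if (pij > 0)
          value <- value + pij * log(pij * pz[k] / (pxz[i, k] * pcz[j, k]),
                                     base = logbase)
      }
    }
  }
  structure(list(value = max(0, value), base = base, counts = counts),
            class = "cmi_estimate")
}

#' @export
print.cmi_estimate <- function(x, ...) {
  unit <- if (x$base == "2") "bits" else "nats"
  cat(sprintf("plug-in (conditional) mutual information: %.4f %s\n",
              x$value, unit))
  invisible(x)
}

#' Relevant-independency table for a conditioning feature
#'
#' Computes `RI(f_i, C; f_given) = I(f_i; C | f_given)` for every feature
#' `f_i` other than the conditioning one, on a discretized dataset. A large
#' RI means `f_i` still predicts the class once `f_given` is known, i.e.
#' the two features are relevant but independent with respect to the class.
#'
#' @param ds a [labeled_dataset()] with discrete (integer-coded) values,
#'   e.g. the `dataset` element of [discretize_nine_level()].
#' @param given index (1-based) of the conditioning feature.
#' @param base log base, see [conditional_mi()].
#' @return data.frame with columns `feature`, `name`, `ri`, sorted by
#'   feature index.
#' @export
ri_table <- function(ds, given, base = c("2", "e")) {
  base <- match.arg(base)
  stopifnot(inherits(ds, "labeled_dataset"))
  given <- as.integer(given)
  if (given < 1L || given > n_features(ds)) stop("conditioning feature out of range")
  others <- setdiff(seq_len(n_features(ds)), given)
  ri <- vapply(others, function(i)
    conditional_mi(ds$values[, i], ds$labels, ds$values[, given], base)$value,
    numeric(1))
  data.frame(feature = others, name = ds$feature_names[others], ri = ri)
}
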