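#' Specification for the synthetic benchmark generator
#'
#' Describes a labeled dataset with four kinds of features, mirroring the
#' structures that motivate modularity-based subset selection:
#' \describe{
#'   \item{group pairs}{XOR-like pairs: each member sits at one of two modes
#'     (+1/-1 plus Gaussian jitter of `noise_sd`) and the class parity is
#'     carried by the \emph{sign product} of the pair, so each member alone
#'     is uninformative about the class while the pair jointly determines
#'     it.}
#'   \item{informative}{individually discriminative features with
#'     unit-spaced class means (class code c has mean c) and within-class
#'     standard deviation 0.5.}
#'   \item{redundant}{near-copies of informative features (cycled) plus
#'     N(0, 0.1) jitter.}
#'   \item{noise}{standard normal, independent of the class.}
#' }
#'
#' @param samples_per_class samples drawn for each class.
#' @param n_classes number of classes (>= 2). Group pairs discriminate the
#'   class \emph{parity} (code mod 2).
#' @param n_group_pairs number of XOR-like pairs (2 features each).
#' @param n_informative number of individually informative features.
#' @param n_redundant number of redundant near-copies; requires
#'   `n_informative >= 1`.
#' @param n_noise number of pure-noise features.
#' @param noise_sd jitter around the +/-1 modes of group-pair members.
#' @param seed RNG seed; the same spec and seed reproduce the dataset
#'   exactly.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(samples_per_class = 150L, n_classes = 2L,
                           n_group_pairs = 1L, n_informative = 3L,
                           n_redundant = 2L, n_noise = 3L,
                           noise_sd = 0.3, seed = 1L) {
  spec <- list(samples_per_class = as.integer(samples_per_class),
               n_classes = as.integer(n_classes),
               n_group_pairs = as.integer(n_group_pairs),
               n_informative = as.integer(n_informative),
               n_redundant = as.integer(n_redundant),
               n_noise = as.integer(n_noise),
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed))
  counts <- unlist(spec[c("samples_per_class", "n_group_pairs",
                          "n_informative", "n_redundant", "n_noise")])
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (spec$n_classes < 2L) stop("class count must be >= 2")
  if (spec$samples_per_class < 1L) stop("samples_per_class must be >= 1")
  n_feat <- 2L * spec$n_group_pairs + spec$n_informative +
    spec$n_redundant + spec$n_noise
  if (n_feat < 1L) stop("total features must be >= 1")
  if (spec$n_redundant > 0L && spec$n_informative == 0L)
    stop("redundant copies require at least one informative feature")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic labeled dataset
#'
#' Realizes a [synthetic_spec()] deterministically under its seed. Feature
#' roles are recorded in the `"feature_roles"` attribute of the returned
#' dataset (`"group"`, `"informative"`, `"redundant"`, `"noise"`), which
#' the benchmark utilities use to score selection traces.
#'
#' @param spec a `synthetic_spec`.
#' @return A [labeled_dataset()] with classes in block order
#'   (`samples_per_class` rows per class).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$samples_per_class * spec$n_classes
  y <- rep(0:(spec$n_classes - 1L), each = spec$samples_per_class)
  parity <- ifelse(y %% 2L == 1L, 1, -1)

  cols <- list(); names_out <- character(0); roles <- character(0)
  for (p in seq_len(spec$n_group_pairs)) {
    s1 <- sample(c(-1, 1), m, replace = TRUE)
    s2 <- s1 * parity
    cols <- c(cols, list(s1 + stats::rnorm(m, 0, spec$noise_sd),
                         s2 + stats::rnorm(m, 0, spec$noise_sd)))
    names_out <- c(names_out, paste0("pair", p, c("_a", "_b")))
    roles <- c(roles, "group", "group")
  }
  inf_cols <- list()
  for (j in seq_len(spec$n_informative)) {
    inf_cols[[j]] <- y + stats::rnorm(m, 0, 0.5)
    names_out <- c(names_out, paste0("inf", j))
    roles <- c(roles, "informative")
  }
  cols <- c(cols, inf_cols)
  for (j in seq_len(spec$n_redundant)) {
    src <- ((j - 1L) %% spec$n_informative) + 1L
    cols <- c(cols, list(inf_cols[[src]] + stats::rnorm(m, 0, 0.1)))
    names_out <- c(names_out, paste0("red", j))
    roles <- c(roles, "redundant")
  }
  for (j in seq_len(spec$n_noise)) {
    cols <- c(cols, list(stats::rnorm(m)))
    names_out <- c(names_out, paste0("noise", j))
    roles <- c(roles, "noise")
  }
  values <- do.call(cbind, cols)
  ds <- labeled_dataset(values, y, names_out,
                        as.character(0:(spec$n_classes - 1L)))
  attr(ds, "feature_roles") <- stats::setNames(roles, names_out)
  ds
}

#' Feature roles of a synthetic dataset
#' @param ds a dataset produced by [generate_synthetic()].
#' @return Named character vector of roles, or NULL for other datasets.
#' @export
feature_roles <- function(ds) attr(ds, "feature_roles")
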