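# Population diversity analytics: pairwise Tanimoto similarity and its
# cumulative distribution, parent-mutant similarity, standardized
# descriptor PCA, and histogram Kullback-Leibler divergence between
# sampled distributions.

#' Pairwise Tanimoto similarity CDF of a population
#'
#' Computes all n(n-1)/2 unordered pairwise similarities on circular
#' fingerprints and returns the empirical cumulative distribution.
#'
#' @param population list of valid `molecule_record`s (>= 2).
#' @return data frame with columns `similarity` (sorted) and `cdf`
#'   (cumulative probability, ending at 1).
#' @export
pairwise_similarity_cdf <- function(population) {
  population <- Filter(function(r) isTRUE(r$valid), population)
  n <- length(population)
  if (n < 2L) stop("need at least two valid molecules")
  fps <- lapply(population, fingerprint)
  sims <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      sims[k] <- tanimoto(fps[[i]], fps[[j]])
    }
  }
  sims <- sort(sims)
  data.frame(similarity = sims, cdf = seq_along(sims) / length(sims))
}

#' Parent-mutant Tanimoto similarities
#'
#' One similarity per aligned valid parent/mutant pair, plus the mean -
#' the per-operator conservation-of-structure summary.
#'
#' @param parents list of valid `molecule_record`s.
#' @param mutants aligned list of `mutation_record`s or `molecule_record`s.
#' @return list with `similarities` (one per valid pair), `mean` and
#'   `n_pairs`.
#' @export
parent_mutant_similarity <- function(parents, mutants) {
  stopifnot(length(parents) == length(mutants))
  sims <- numeric()
  for (i in seq_along(parents)) {
    m <- mutants[[i]]
    if (inherits(m, "mutation_record")) m <- m$record
    if (isTRUE(parents[[i]]$valid) && isTRUE(m$valid)) {
      sims <- c(sims, tanimoto(fingerprint(parents[[i]]), fingerprint(m)))
    }
  }
  if (!length(sims)) stop("no valid parent/mutant pairs")
  list(similarities = sims, mean = mean(sims), n_pairs = length(sims))
}

#' Standardized two-component PCA of a descriptor table
#'
#' Columns are standardized to zero mean and unit variance (zero-variance
#' columns are dropped with a warning) before the decomposition. The sign
#' convention fixes the largest-magnitude loading of each component to be
#' positive.
#'
#' @param table data frame or matrix of descriptors (>= 3 rows); an `id`
#'   column, if present, is carried through to the scores.
#' @param n_components number of components (default 2).
#' @return object of class `pca_result` with `loadings` (columns
#'   orthonormal), `scores`, `explained_variance_ratio` and the dropped
#'   column names.
#' @export
pca_fit <- function(table, n_components = 2L) {
  ids <- NULL
  if (is.data.frame(table) && "id" %in% names(table)) {
    ids <- table$id
    table <- table[setdiff(names(table), "id")]
  }
  X <- as.matrix(table)
  if (nrow(X) < 3L) stop("need at least three rows for PCA")
  sds <- apply(X, 2L, stats::sd)
  drop <- colnames(X)[sds < 1e-12]
  if (length(drop)) {
    warning("dropping zero-variance columns: ", paste(drop, collapse = ", "))
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  if (ncol(X) < n_components) stop("fewer informative columns than components")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  L <- pc$rotation[, seq_len(n_components), drop = FALSE]
  S <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      S[, j] <- -S[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = L, scores = S,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 dropped = drop, ids = ids),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, explained variance %s\n",
              ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = " + ")))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Histogram Kullback-Leibler divergence between two samples
#'
#' Estimates `D_KL(P || Q) = sum_x P(x) ln(P(x) / Q(x))` from two samples
#' by binning both over their shared min-max range (`n_bins` equal-width
#' bins, default 50), adding `epsilon` (default 1e-10) to every bin
#' before normalization, and using the natural logarithm. The estimate is
#' non-negative and exactly zero when both samples induce identical
#' histograms. The convention throughout the benchmark is
#' `P` = original population, `Q` = mutated population.
#'
#' @param sample_p,sample_q numeric samples (non-empty, finite).
#' @param n_bins number of shared-range bins.
#' @param epsilon smoothing constant added to each bin count.
#' @return object of class `kl_estimate` with `value` (nats), `n_bins`,
#'   `epsilon` and the shared `support`.
#' @export
kl_divergence <- function(sample_p, sample_q, n_bins = 50L, epsilon = 1e-10) {
  if (!length(sample_p) || !length(sample_q)) stop("samples must be non-empty")
  if (!all(is.finite(sample_p)) || !all(is.finite(sample_q))) {
    stop("samples must be finite")
  }
  lo <- min(sample_p, sample_q)
  hi <- max(sample_p, sample_q)
  if (hi <= lo) hi <- lo + 1e-9 # all values identical: one effective bin
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  hp <- .bin_counts(sample_p, breaks)
  hq <- .bin_counts(sample_q, breaks)
  p <- (hp + epsilon) / sum(hp + epsilon)
  q <- (hq + epsilon) / sum(hq + epsilon)
  value <- sum(p * log(p / q))
  structure(list(value = max(0, value), n_bins = as.integer(n_bins),
                 epsilon = epsilon, support = c(lo, hi)),
            class = "kl_estimate")
}

.bin_counts <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, length(breaks) - 1L)
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("<kl_estimate> %.4f nats (%d bins over [%.3g, %.3g], eps=%g)\n",
              x$value, x$n_bins, x$support[1], x$support[2], x$epsilon))
  invisible(x)
}
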