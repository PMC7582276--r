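#' Fit a PCA-based domain-adaptation (PDA) projection
#'
#' Learns an orthonormal projection from historical (source) trials only:
#' the source features are centred at their mean and the eigenvectors of the
#' source covariance corresponding to the `d` largest eigenvalues form the
#' projected feature space, with `d` the smallest dimension retaining at
#' least `variance_threshold` of the total variance (90% by default).  The
#' same map -- same mean, same eigenvectors -- is later applied unchanged to
#' incoming test trials, so no statistic of the target data ever influences
#' the basis: the adaptation is purely unsupervised and source-driven.
#'
#' The eigenvector sign is fixed so that the largest-magnitude entry of each
#' column is positive, making repeated fits bit-identical.
#'
#' @param source_features Numeric matrix, trials x features (>= 2 trials).
#' @param variance_threshold Fraction of variance to retain, in (0, 1].
#' @return An object of class `pda_basis` with fields `mean`, `Ms`
#'   (features x d eigenvector matrix), `d`, `eigenvalues` (the d leading
#'   eigenvalues, non-increasing), `variance_retained`, `threshold`, and
#'   `n_features`.
#' @export
#' @examples
#' X <- rbind(c(0, 0), c(2, 0), c(0, 1), c(2, 1))
#' fit_pda(X, 0.7)$d # the leading axis already explains 80% of the variance
fit_pda <- function(source_features, variance_threshold = 0.9) {
  X <- as.matrix(source_features)
  if (nrow(X) < 2L) .stopf("need at least 2 source trials to fit a basis")
  if (ncol(X) < 1L) .stopf("need at least 1 feature")
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1) {
    .stopf("`variance_threshold` must be in (0, 1]")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= 0) .stopf("source data have zero total variance")
  frac <- cumsum(ev) / total
  d <- which(frac >= variance_threshold - 1e-12)[1]
  if (is.na(d)) d <- length(ev)
  Ms <- pc$rotation[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(d)) {
    i <- which.max(abs(Ms[, j]))
    if (Ms[i, j] < 0) Ms[, j] <- -Ms[, j]
  }
  structure(
    list(
      mean = pc$center, Ms = Ms, d = as.integer(d),
      eigenvalues = ev[seq_len(d)], variance_retained = frac[d],
      threshold = variance_threshold, n_features = ncol(X)
    ),
    class = "pda_basis"
  )
}

#' Project samples into a fitted PDA feature space
#'
#' Centers `samples` at the *source* mean stored in the basis and multiplies
#' by the eigenvector matrix: `Z = (X - mean) %*% Ms`.  Applying the map to
#' the source data yields scores whose per-column variances equal the
#' retained eigenvalues.
#'
#' @param basis A `pda_basis` from [fit_pda()].
#' @param samples Numeric matrix (trials x features) or a single feature
#'   vector; the feature count must match the basis.
#' @return A trials x d score matrix (a 1-row matrix for a vector input).
#' @export
pda_project <- function(basis, samples) {
  stopifnot(inherits(basis, "pda_basis"))
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  samples <- as.matrix(samples)
  if (ncol(samples) != basis$n_features) {
    .stopf("sample feature count (%d) does not match basis (%d)",
           ncol(samples), basis$n_features)
  }
  sweep(samples, 2L, basis$mean, "-") %*% basis$Ms
}

#' @export
print.pda_basis <- function(x, ...) {
  cat(sprintf(
    "<pda_basis> %d -> %d dims, %.1f%% variance retained (threshold %.0f%%)\n",
    x$n_features, x$d, 100 * x$variance_retained, 100 * x$threshold
  ))
  invisible(x)
}
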