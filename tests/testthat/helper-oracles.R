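# Independent loop-based oracles, written against the update equations
# directly (scalar arithmetic, no vectorisation, no shared helpers) so they
# can check the package's vectorised and compiled paths.

# scalar forward pass: returns gamma (incl. bias), drives, probabilities
oracle_forward <- function(v, w, x) {
  n_in <- nrow(v) - 1L
  M <- ncol(v)
  C <- ncol(w)
  xf <- c(1, x)
  gamma <- numeric(M + 1L)
  gamma[1] <- 1
  for (j in seq_len(M)) {
    h <- 0
    for (i in seq_len(n_in + 1L)) h <- h + v[i, j] * xf[i]
    gamma[j + 1L] <- 1 / (1 + exp(-h))
  }
  a <- numeric(C)
  for (k in seq_len(C)) {
    for (j in seq_len(M + 1L)) a[k] <- a[k] + w[j, k] * gamma[j]
  }
  e <- exp(a - max(a))
  list(gamma = gamma, a = a, p = e / sum(e))
}

# elementwise single-trial Hebbian update with pre-update feedback weights
oracle_update <- function(v, w, x, gamma, s, f, beta) {
  M <- ncol(v)
  C <- ncol(w)
  xf <- c(1, x)
  w_new <- w
  for (j in seq_len(M + 1L)) {
    for (k in seq_len(C)) {
      z <- if (k == s) 1 else 0
      w_new[j, k] <- w[j, k] + beta * gamma[j] * z * f
    }
  }
  v_new <- v
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(M)) {
      gj <- gamma[j + 1L]
      v_new[i, j] <- v[i, j] + beta * xf[i] * gj * f * (w[j + 1L, s] * (1 - gj))
    }
  }
  list(v = v_new, w = w_new)
}

# summed mini-batch update (pass-entry weights throughout), given winners
oracle_mb_update <- function(v, w, X, winners, f, beta) {
  M <- ncol(v)
  C <- ncol(w)
  dv <- matrix(0, nrow(v), ncol(v))
  dw <- matrix(0, nrow(w), ncol(w))
  for (n in seq_len(nrow(X))) {
    fw <- oracle_forward(v, w, X[n, ])
    s <- winners[n]
    xf <- c(1, X[n, ])
    for (j in seq_len(M + 1L)) dw[j, s] <- dw[j, s] + beta * fw$gamma[j] * f[n]
    for (i in seq_len(nrow(v))) {
      for (j in seq_len(M)) {
        gj <- fw$gamma[j + 1L]
        dv[i, j] <- dv[i, j] + beta * xf[i] * gj * f[n] * (w[j + 1L, s] * (1 - gj))
      }
    }
  }
  list(v = v + dv, w = w + dw)
}

# small random network weights in the standard +-0.1 init range
random_weights <- function(n_in, M, C, range = 0.1) {
  structure(
    list(v = matrix(runif((n_in + 1) * M, -range, range), n_in + 1, M),
         w = matrix(runif((M + 1) * C, -range, range), M + 1, C)),
    class = "agrel_weights"
  )
}

# three well-separated Gaussian clusters in 2-D; returns features and labels
toy_clusters <- function(n_per_class = 20, sep = 6, sd = 0.5) {
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(cl) {
    cbind(rnorm(n_per_class, centers[cl, 1], sd),
          rnorm(n_per_class, centers[cl, 2], sd))
  }))
  list(X = X, y = rep(1:3, each = n_per_class))
}

# nearest-class-mean linear readout used to probe simulator separability
centroid_fit <- function(X, y) {
  t(sapply(sort(unique(y)), function(cl) colMeans(X[y == cl, , drop = FALSE])))
}
centroid_predict <- function(centers, X) {
  d2 <- sapply(seq_len(nrow(centers)), function(cl) {
    rowSums(sweep(X, 2, centers[cl, ])^2)
  })
  max.col(-d2, ties.method = "first")
}

scaled_sim <- function(seed, n_days = 2, drift_sigma = 0.3, ...) {
  sim_config(n_channels = 20, trials_per_class_per_day = 40,
             n_days = n_days, drift_sigma = drift_sigma, seed = seed, ...)
}

# fresh scratch directory per call, cleaned up by testthat's temp handling
withr_like_tempdir <- function() {
  d <- tempfile("tmagrl-test-")
  dir.create(d)
  d
}
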