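#' Training configuration for the initial decoder
#'
#' @param k Confidence gate threshold: a trial whose true-class probability
#'   already exceeds `k` triggers no weight update (default 0.9).
#' @param convergence_fraction Fraction of training trials that must be above
#'   the gate for the model to be declared convergent (default 0.98).
#' @param max_epochs Epoch cap (default 1000).
#' @param repeats Number of runs in repeated-run studies (default 50).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `training_config`.
#' @export
training_config <- function(k = 0.9, convergence_fraction = 0.98,
                            max_epochs = 1000, repeats = 50, seed = NULL) {
  if (k <= 0 || k >= 1) .stopf("`k` must be in (0, 1)")
  if (convergence_fraction <= 0 || convergence_fraction > 1) {
    .stopf("`convergence_fraction` must be in (0, 1]")
  }
  .check_count(max_epochs, "max_epochs")
  .check_count(repeats, "repeats")
  structure(
    list(k = k, convergence_fraction = convergence_fraction,
         max_epochs = as.integer(max_epochs), repeats = as.integer(repeats),
         seed = seed),
    class = "training_config"
  )
}

#' Per-trial probability of the correct action
#'
#' Deterministic forward pass over all trials: for each one, the softmax
#' probability the network assigns to the true class (no action sampling).
#'
#' @param weights An `agrel_weights` object.
#' @param X Trials x inputs matrix.
#' @param y Integer labels in `1..n_outputs`.
#' @return Numeric vector of `P(correct)` per trial, each in `[0, 1]`.
#' @export
confidence <- function(weights, X, y) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(weights$v) - 1L) .stopf("input/weight shape mismatch")
  .check_labels(y, ncol(weights$w))
  P <- .probs_matrix(weights, X)
  P[cbind(seq_len(nrow(X)), y)]
}

#' Root-mean-square error between class probabilities and one-hot labels
#'
#' The RMS over all trials and classes of the difference between the output
#' probability vector and the one-hot true-label vector; the training-
#' efficiency measure recorded per epoch.
#'
#' @inheritParams confidence
#' @return A nonnegative scalar (at most `sqrt(2)`).
#' @export
training_rms <- function(weights, X, y) {
  X <- as.matrix(X)
  .check_labels(y, ncol(weights$w))
  P <- .probs_matrix(weights, X)
  Yh <- matrix(0, nrow(P), ncol(P))
  Yh[cbind(seq_len(nrow(P)), y)] <- 1
  sqrt(mean((P - Yh)^2))
}

#' Train the initial decoder on historical data
#'
#' Implements the confidence-gated training flow.  If `use_pda` is `TRUE`,
#' a PDA basis is fitted on the historical features (retaining
#' `variance_threshold` of the variance) and training runs on the projected
#' data; this is the TMAGRL initial decoder.  Each epoch visits all trials
#' in a freshly shuffled order; a trial whose current `P(correct)` exceeds
#' `k` is skipped, otherwise the network samples an action, receives reward
#' (`1` iff the winner equals the label), and applies the single-trial
#' Hebbian update.  After each epoch the convergence criterion is checked:
#' the model is convergent when at least `convergence_fraction` of trials
#' select the correct action with probability above `k`.  If `max_epochs` is
#' reached without convergence, the best epoch's snapshot (highest training
#' accuracy under most-probable-class prediction; earliest epoch on ties) is
#' returned instead of the final weights.
#'
#' @param X Historical trials x features matrix (raw counts).
#' @param y Integer labels in `1..n_classes` (at least one trial per class,
#'   at least two classes).
#' @param config Optional [agrel_config()]; defaults to a 30-hidden-unit
#'   network sized to the (projected) input dimension and `max(y)` outputs.
#' @param training A [training_config()].
#' @param use_pda Fit and train through a PDA projection?
#' @param gate Apply the per-trial confidence gate (disable for the plain
#'   AGREL configuration, which updates on every trial)?
#' @param variance_threshold Variance retained by the PDA basis (default 0.9).
#' @return An object of class `decoder_model`: list with `weights`, `basis`
#'   (`NULL` without PDA), `config`, `training`, `epochs_run`, `converged`,
#'   `best_epoch`, and a per-epoch `history` data frame (fraction above the
#'   gate, training accuracy, RMS).
#' @export
train_initial <- function(X, y, config = NULL, training = training_config(),
                          use_pda = TRUE, gate = TRUE,
                          variance_threshold = 0.9) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) .stopf("feature/label length mismatch")
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    .stopf("degenerate input: need at least two classes")
  }
  with_seed(training$seed, {
    basis <- NULL
    Xin <- X
    if (use_pda) {
      basis <- fit_pda(X, variance_threshold)
      Xin <- pda_project(basis, X)
    }
    if (is.null(config)) {
      config <- agrel_config(n_inputs = ncol(Xin), n_outputs = max(y))
    }
    if (config$n_inputs != ncol(Xin)) {
      .stopf("config expects %d inputs but training data have %d",
             config$n_inputs, ncol(Xin))
    }
    .check_labels(y, config$n_outputs)
    weights <- init_weights(config)
    res <- train_agrel_cpp(
      Xin, y, weights$v, weights$w, config$beta, training$k,
      training$convergence_fraction, training$max_epochs,
      config$reward_value, config$f_max / (1 + config$f_max),
      gate, TRUE
    )
    final <- if (res$converged) {
      structure(list(v = res$v, w = res$w), class = "agrel_weights")
    } else {
      structure(list(v = res$best_v, w = res$best_w), class = "agrel_weights")
    }
    structure(
      list(
        weights = final, basis = basis, config = config, training = training,
        gate = gate, epochs_run = res$epochs_run, converged = res$converged,
        best_epoch = if (res$converged) res$epochs_run else res$best_epoch,
        history = data.frame(
          epoch = seq_len(res$epochs_run),
          frac_above_k = as.numeric(res$frac_hist),
          accuracy = as.numeric(res$acc_hist),
          rms = as.numeric(res$rms_hist)
        )
      ),
      class = "decoder_model"
    )
  })
}

#' Epoch-wise RMS training-efficiency study
#'
#' Trains fresh networks for a fixed number of epochs with no early stopping
#' and no confidence gate (every trial updates every epoch), recording the
#' training RMS after each epoch, and repeats the whole run `repeats` times
#' with fresh initialisations to obtain a mean curve with a standard
#' deviation.  `method = "tmagrl"` trains on PDA-projected features,
#' `method = "agrel"` on the raw features; the contrast isolates the effect
#' of the projection on training efficiency.
#'
#' @param X,y Historical data as in [train_initial()].
#' @param method `"tmagrl"` or `"agrel"`.
#' @param epochs Number of epochs per run (default 1000).
#' @param repeats Number of repeated runs (default 50).
#' @param config Optional [agrel_config()].
#' @param seed Optional master seed.
#' @param variance_threshold PDA variance threshold (default 0.9).
#' @return A data frame (class `rms_study`) with columns `epoch`, `mean`,
#'   `sd`, and the per-repeat RMS matrix in attribute `rms`.
#' @export
rms_convergence_study <- function(X, y, method = c("tmagrl", "agrel"),
                                  epochs = 1000, repeats = 50, config = NULL,
                                  seed = NULL, variance_threshold = 0.9) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.integer(y)
  .check_count(epochs, "epochs")
  .check_count(repeats, "repeats")
  with_seed(seed, {
    Xin <- X
    if (method == "tmagrl") {
      Xin <- pda_project(fit_pda(X, variance_threshold), X)
    }
    if (is.null(config)) {
      config <- agrel_config(n_inputs = ncol(Xin), n_outputs = max(y))
    }
    rms <- matrix(NA_real_, repeats, epochs)
    for (r in seq_len(repeats)) {
      weights <- init_weights(config)
      res <- train_agrel_cpp(
        Xin, y, weights$v, weights$w, config$beta, 0.9, 1.01, epochs,
        config$reward_value, config$f_max / (1 + config$f_max),
        FALSE, FALSE
      )
      rms[r, ] <- as.numeric(res$rms_hist)
    }
    out <- data.frame(
      epoch = seq_len(epochs),
      mean = colMeans(rms),
      sd = if (repeats == 1L) rep(0, epochs) else apply(rms, 2L, stats::sd)
    )
    attr(out, "rms") <- rms
    attr(out, "method") <- method
    class(out) <- c("rms_study", "data.frame")
    out
  })
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model> %s%d inputs -> %d hidden -> %d outputs; %s after %d epochs\n",
    if (is.null(x$basis)) "" else sprintf("PDA %d -> ", x$basis$n_features),
    x$config$n_inputs, x$config$n_hidden, x$config$n_outputs,
    if (x$converged) "converged" else
      sprintf("not converged (best epoch %d)", x$best_epoch),
    x$epochs_run
  ))
  invisible(x)
}
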