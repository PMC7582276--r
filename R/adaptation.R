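#' Online-adaptation configuration
#'
#' @param J Mini-batch size: capacity of the FIFO buffer of the latest tested
#'   samples (default 30; `Inf` uses all tested samples, the full-batch
#'   configuration).
#' @param k Confidence gate threshold shared with training (default 0.9).
#' @param convergence_fraction Fraction of buffered samples that must be
#'   confidently correct for the inner update loop to stop (default 0.98).
#' @param max_update_epochs Cap on update passes per tested trial
#'   (default 50), bounding per-trial latency.
#' @param beta Learning rate for online updates (default 0.01).
#' @param gate Apply the confidence gate and convergence-driven inner loop?
#'   With `gate = FALSE` (plain AGREL) every trial triggers exactly one
#'   full-buffer update pass.
#' @return An object of class `adaptation_config`.
#' @export
adaptation_config <- function(J = 30, k = 0.9, convergence_fraction = 0.98,
                              max_update_epochs = 50, beta = 0.01,
                              gate = TRUE) {
  if (!(is.infinite(J) && J > 0)) .check_count(J, "J")
  if (k <= 0 || k >= 1) .stopf("`k` must be in (0, 1)")
  if (convergence_fraction <= 0 || convergence_fraction > 1) {
    .stopf("`convergence_fraction` must be in (0, 1]")
  }
  .check_count(max_update_epochs, "max_update_epochs")
  if (beta <= 0) .stopf("`beta` must be positive")
  structure(
    list(J = J, k = k, convergence_fraction = convergence_fraction,
         max_update_epochs = as.integer(max_update_epochs), beta = beta,
         gate = isTRUE(gate)),
    class = "adaptation_config"
  )
}

#' Create an empty FIFO mini-batch buffer
#'
#' @param capacity Maximum number of (features, label) pairs held (may be
#'   `Inf`).
#' @return An object of class `mb_buffer` with fields `X` (rows newest last),
#'   `y`, and `capacity`.
#' @export
mb_buffer <- function(capacity = 30) {
  if (!(is.infinite(capacity) && capacity > 0)) .check_count(capacity, "capacity")
  structure(list(X = NULL, y = integer(0), capacity = capacity),
            class = "mb_buffer")
}

#' Push a tested sample into the buffer
#'
#' Appends the sample; once the buffer is full the oldest entry is evicted,
#' so after `t` pushes the buffer holds exactly the latest `min(t, capacity)`
#' samples in order.
#'
#' @param buffer An `mb_buffer`.
#' @param x Feature vector of the tested trial.
#' @param label Its true class.
#' @return The updated buffer.
#' @export
mb_push <- function(buffer, x, label) {
  stopifnot(inherits(buffer, "mb_buffer"))
  if (!is.null(buffer$X) && length(x) != ncol(buffer$X)) {
    .stopf("sample dimension %d does not match buffer (%d)",
           length(x), ncol(buffer$X))
  }
  X <- rbind(buffer$X, matrix(x, nrow = 1L))
  y <- c(buffer$y, as.integer(label))
  if (nrow(X) > buffer$capacity) {
    keep <- seq.int(nrow(X) - buffer$capacity + 1L, nrow(X))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  structure(list(X = X, y = y, capacity = buffer$capacity), class = "mb_buffer")
}

#' @export
length.mb_buffer <- function(x) length(x$y)

#' One mini-batch update pass over the buffer
#'
#' All buffered samples are forwarded with the pass-entry weights; for each
#' one an action is sampled from its softmax, rewarded against the stored
#' label, and converted to `f(delta)`.  The per-sample Hebbian contributions
#' are summed -- `dw_jk = beta * sum_n gamma_j^n Z_k^n f(delta_n)` for the
#' output weights and `dv_ij = beta * sum_n x_i^n gamma_j^n f(delta_n) *
#' [w_js_n (1 - gamma_j^n)]` with pass-entry feedback weights -- and the
#' summed update is applied once.  With a single buffered sample this reduces
#' exactly to [single_trial_update()].
#'
#' @param weights An `agrel_weights` object.
#' @param buffer A non-empty `mb_buffer`.
#' @param beta Learning rate.
#' @param reward_value,f_max See [agrel_config()].
#' @return A new `agrel_weights` object.
#' @export
mb_update_pass <- function(weights, buffer, beta = 0.01, reward_value = 1,
                           f_max = 99) {
  stopifnot(inherits(buffer, "mb_buffer"))
  m <- length(buffer)
  if (m == 0L) .stopf("buffer is empty")
  Bx <- cbind(1, buffer$X)
  G <- .sigmoid(Bx %*% weights$v)
  Gf <- cbind(1, G)
  P <- .softmax_rows(Gf %*% weights$w)
  M <- ncol(weights$v)
  C <- ncol(weights$w)
  dcap <- f_max / (1 + f_max)
  u <- runif(m) # one draw per buffered sample, in buffer order
  f <- numeric(m)
  Zf <- matrix(0, m, C)
  Wsel <- matrix(0, m, M)
  for (i in seq_len(m)) {
    s <- min(findInterval(u[i], cumsum(P[i, ])) + 1L, C)
    rewarded <- s == buffer$y[i]
    delta <- if (rewarded) reward_value * (1 - P[i, s]) else -1
    d <- if (delta < 0) delta else min(delta, dcap)
    f[i] <- if (d < 0) -1 else d / (1 - d)
    Zf[i, s] <- f[i]
    Wsel[i, ] <- weights$w[-1, s]
  }
  Coef <- G * (1 - G) * Wsel * f
  structure(
    list(v = weights$v + beta * crossprod(Bx, Coef),
         w = weights$w + beta * crossprod(Gf, Zf)),
    class = "agrel_weights"
  )
}

#' Test one trial and adapt the decoder (R reference path)
#'
#' Single-trial version of the adaptive testing loop: forward pass and
#' stochastic action selection give the prediction and reward; the sample
#' (with its label) enters the FIFO buffer regardless of gating; if the
#' decoder already assigns the true class probability above `k` no update
#' occurs, otherwise mini-batch passes repeat until at least
#' `convergence_fraction` of the buffered samples are confidently correct or
#' `max_update_epochs` passes have run.  [run_online()] streams a whole
#' session through the equivalent compiled loop.
#'
#' @param model A `decoder_model` (or bare `agrel_weights`).
#' @param buffer An `mb_buffer`.
#' @param x The trial's input vector, already in the model's input space
#'   (callers apply [pda_project()] for TMAGRL).
#' @param true_label The trial's class.
#' @param config An [adaptation_config()].
#' @return List with `predicted`, `reward`, `gated`, `update_passes`, and the
#'   updated `model` and `buffer`.
#' @export
test_and_adapt <- function(model, buffer, x, true_label,
                           config = adaptation_config()) {
  weights <- if (inherits(model, "agrel_weights")) model else model$weights
  fw <- agrel_forward(weights, x)
  act <- select_action(fw$p)
  rewarded <- act$winner == true_label
  buffer <- mb_push(buffer, x, true_label)
  gated <- config$gate && fw$p[true_label] > config$k
  passes <- 0L
  if (!gated) {
    repeat {
      weights <- mb_update_pass(weights, buffer, config$beta)
      passes <- passes + 1L
      if (!config$gate) break
      frac <- mean(confidence(weights, buffer$X, buffer$y) > config$k)
      if (frac >= config$convergence_fraction ||
          passes >= config$max_update_epochs) {
        break
      }
    }
  }
  if (inherits(model, "agrel_weights")) {
    model <- weights
  } else {
    model$weights <- weights
  }
  list(predicted = act$winner, reward = if (rewarded) 1 else 0,
       gated = gated, update_passes = passes, model = model, buffer = buffer)
}

#' Stream a test session through the decoder
#'
#' Presents the session's trials in order.  Each trial is predicted by
#' stochastic action selection; with `adapt = TRUE` the confidence-gated
#' mini-batch updating recalibrates the weights as testing proceeds, while
#' `adapt = FALSE` realises the non-adaptive (NAGREL-style) protocol and
#' leaves the weights untouched.  If the model carries a PDA basis the
#' features are projected into its space first.
#'
#' @param model A `decoder_model` from [train_initial()].
#' @param session A `session_dataset` (or list with `features` and `labels`).
#' @param config An [adaptation_config()].
#' @param adapt Update weights online?
#' @return An object of class `online_result`: list with `trace` (data frame:
#'   trial, true, predicted, reward, gated, update_passes), `accuracy`, and
#'   the final `model`.
#' @export
run_online <- function(model, session, config = adaptation_config(),
                       adapt = TRUE) {
  stopifnot(inherits(model, "decoder_model"))
  X <- as.matrix(session$features)
  y <- as.integer(session$labels)
  if (!is.null(model$basis)) X <- pda_project(model$basis, X)
  if (ncol(X) != model$config$n_inputs) {
    .stopf("test dimension %d does not match model inputs (%d)",
           ncol(X), model$config$n_inputs)
  }
  .check_labels(y, model$config$n_outputs)
  J <- if (is.infinite(config$J)) nrow(X) else min(config$J, nrow(X))
  res <- run_online_cpp(
    X, y, model$weights$v, model$weights$w, as.integer(J), config$k,
    config$convergence_fraction, config$max_update_epochs, config$beta,
    model$config$reward_value,
    model$config$f_max / (1 + model$config$f_max), adapt, config$gate
  )
  model$weights <- structure(list(v = res$v, w = res$w),
                             class = "agrel_weights")
  trace <- data.frame(
    trial = seq_along(y), true = y, predicted = as.integer(res$pred),
    reward = as.numeric(res$reward), gated = as.logical(res$gated),
    update_passes = as.integer(res$passes)
  )
  structure(
    list(trace = trace, accuracy = mean(trace$predicted == trace$true),
         model = model),
    class = "online_result"
  )
}

#' @export
print.online_result <- function(x, ...) {
  cat(sprintf(
    "<online_result> %d trials, accuracy %.3f, %d updated trials (mean %.1f passes)\n",
    nrow(x$trace), x$accuracy, sum(x$trace$update_passes > 0),
    mean(x$trace$update_passes)
  ))
  invisible(x)
}
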