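#' Configuration of the attention-gated RL network
#'
#' The decoder is a three-layer network: `n_inputs` input units (plus a bias
#' unit clamped to 1), `n_hidden` sigmoid hidden units (plus a bias unit),
#' and `n_outputs` output units read out through a stochastic softmax.
#'
#' @param n_inputs Input dimension (post-projection `d` for TMAGRL, raw
#'   feature count for plain AGREL).
#' @param n_hidden Hidden units (default 30).
#' @param n_outputs Output classes (default 3).
#' @param beta Learning rate (default 0.01).
#' @param init_range Half-width of the uniform weight initialisation
#'   (default 0.1, i.e. weights start in (-0.1, 0.1)).
#' @param reward_value Reward delivered on a correct action (default 1).
#' @param f_max Cap on the expansive function; the reward-prediction error is
#'   clipped so `f(delta) <= f_max` (default 99), bounding the update when a
#'   near-zero-probability action happens to be rewarded.
#' @return An object of class `agrel_config`.
#' @export
agrel_config <- function(n_inputs, n_hidden = 30, n_outputs = 3,
                         beta = 0.01, init_range = 0.1, reward_value = 1,
                         f_max = 99) {
  .check_count(n_inputs, "n_inputs")
  .check_count(n_hidden, "n_hidden")
  .check_count(n_outputs, "n_outputs")
  if (beta <= 0) .stopf("`beta` must be positive")
  if (init_range <= 0) .stopf("`init_range` must be positive")
  if (f_max <= 0) .stopf("`f_max` must be positive")
  structure(
    list(n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
         n_outputs = as.integer(n_outputs), beta = beta,
         init_range = init_range, reward_value = reward_value, f_max = f_max),
    class = "agrel_config"
  )
}

#' Initialise network weights
#'
#' Every entry of the input-to-hidden matrix `v` (`(n_inputs + 1) x n_hidden`,
#' row 1 being the bias-unit weights) and of the hidden-to-output matrix `w`
#' (`(n_hidden + 1) x n_outputs`, row 1 the hidden-bias weights) is drawn
#' i.i.d. uniform on `(-init_range, init_range)` from the current RNG stream.
#'
#' @param config An [agrel_config()].
#' @return An object of class `agrel_weights` with matrices `v` and `w`.
#' @export
init_weights <- function(config) {
  stopifnot(inherits(config, "agrel_config"))
  r <- config$init_range
  v <- matrix(runif((config$n_inputs + 1L) * config$n_hidden, -r, r),
              config$n_inputs + 1L, config$n_hidden)
  w <- matrix(runif((config$n_hidden + 1L) * config$n_outputs, -r, r),
              config$n_hidden + 1L, config$n_outputs)
  structure(list(v = v, w = w), class = "agrel_weights")
}

#' Forward pass of the AGREL network
#'
#' Hidden activations are `gamma_j = sigmoid(h_j)` with
#' `h_j = sum_i v_ij x_i` over the inputs including the bias `x_0 = 1`;
#' output drives are `a_k = sum_j w_jk gamma_j` including the hidden bias
#' `gamma_0 = 1`; class probabilities are the (numerically stable) softmax of
#' the drives.
#'
#' @param weights An `agrel_weights` object.
#' @param x Input vector of length `n_inputs` (finite).
#' @return List with `gamma` (length `n_hidden + 1`, `gamma[1] = 1` the bias
#'   unit), `a` (output drives), and `p` (class probabilities summing to 1).
#' @export
agrel_forward <- function(weights, x) {
  if (length(x) != nrow(weights$v) - 1L) {
    .stopf("input length %d does not match network (%d inputs)",
           length(x), nrow(weights$v) - 1L)
  }
  if (any(!is.finite(x))) .stopf("non-finite input")
  xf <- c(1, x)
  h <- drop(xf %*% weights$v)
  gamma <- .sigmoid(h)
  gf <- c(1, gamma)
  a <- drop(gf %*% weights$w)
  list(gamma = gf, a = a, p = .softmax(a))
}

#' Sample the winning output unit
#'
#' Draws the winner `s` from the softmax probabilities: only the winning unit
#' takes activity 1, all others 0.  Uses a single uniform draw from the
#' current RNG stream (inverse-CDF sampling), so traces are reproducible
#' given the stream state.
#'
#' @param p Probability vector (must sum to 1 within 1e-9).
#' @return List with `winner` (index) and `z` (one-hot activity vector).
#' @export
select_action <- function(p) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    .stopf("`p` is not a normalized probability vector")
  }
  u <- runif(1)
  s <- min(findInterval(u, cumsum(p)) + 1L, length(p))
  z <- numeric(length(p))
  z[s] <- 1
  list(winner = s, z = z)
}

#' Reward-prediction error
#'
#' On rewarded trials the error is the obtained minus the expected reward;
#' the expectation of the reward for the selected action is its softmax
#' probability times the reward value, so with unit reward
#' `delta = 1 - p_s`.  Unrewarded trials give the fixed negative feedback
#' `delta = -1`.
#'
#' @param p_s Probability of the selected action, in `[0, 1]`.
#' @param rewarded Logical; was the selected action correct?
#' @param reward_value Reward magnitude (default 1).
#' @return The scalar error `delta`.
#' @export
compute_delta <- function(p_s, rewarded, reward_value = 1) {
  if (!is.finite(p_s) || p_s < 0 || p_s > 1) .stopf("`p_s` must be in [0, 1]")
  if (isTRUE(rewarded)) reward_value * (1 - p_s) else -1
}

#' Expansive function of the reward-prediction error
#'
#' `f(delta) = delta / (1 - delta)` for `delta >= 0` and `f(-1) = -1`:
#' unexpectedly rewarded low-probability actions produce disproportionately
#' large updates, while fully expected rewards produce none.  To keep updates
#' bounded, `delta` is clipped at `f_max / (1 + f_max)` before the ratio
#' (equivalently `f <= f_max`).  Values of `delta` in `(-1, 0)` or `>= 1`
#' violate the error-signal contract and are rejected.
#'
#' @param delta Reward-prediction error (`[0, 1)` or exactly -1).
#' @param f_max Cap on the output (default 99).
#' @return The scalar `f(delta)`.
#' @export
expansive <- function(delta, f_max = 99) {
  if (!is.finite(delta)) .stopf("`delta` must be finite")
  if (delta == -1) return(-1)
  if (delta < 0 || delta >= 1) {
    .stopf("`delta` = %g violates the error-signal contract", delta)
  }
  d <- min(delta, f_max / (1 + f_max))
  d / (1 - d)
}

#' Run one stochastic trial through the network
#'
#' Convenience wrapper chaining [agrel_forward()], [select_action()], reward
#' assignment (`reward_value` iff the winner equals the label),
#' [compute_delta()], and [expansive()].
#'
#' @param weights An `agrel_weights` object.
#' @param x Input vector.
#' @param label True class of the trial.
#' @param reward_value,f_max See [agrel_config()].
#' @return A trial outcome: list with `gamma`, `a`, `p`, `winner`, `z`,
#'   `reward`, `delta`, and `f_delta`.
#' @export
agrel_trial <- function(weights, x, label, reward_value = 1, f_max = 99) {
  fw <- agrel_forward(weights, x)
  act <- select_action(fw$p)
  rewarded <- act$winner == label
  delta <- compute_delta(fw$p[act$winner], rewarded, reward_value)
  list(
    gamma = fw$gamma, a = fw$a, p = fw$p, winner = act$winner, z = act$z,
    reward = if (rewarded) reward_value else 0, delta = delta,
    f_delta = expansive(delta, f_max)
  )
}

#' Single-trial Hebbian weight update
#'
#' Applies the reward-modulated Hebbian rule for one trial.  Output weights:
#' `dw_jk = beta * gamma_j * Z_k * f(delta)` -- only the column of the
#' winning unit `s` changes, including its hidden-bias row.  Hidden weights:
#' `dv_ij = beta * x_i * gamma_j * f(delta) * [w_js * (1 - gamma_j)]`, where
#' the feedback weight `w_js` of the winning unit is taken *before* the
#' output update (both deltas are computed from the pre-update weights and
#' applied simultaneously), and `x_0 = 1` updates the bias row.  Hidden units
#' exciting the winner most strongly receive the strongest feedback -- the
#' attention mechanism that assigns credit for the selected action.
#'
#' @param weights An `agrel_weights` object.
#' @param x The trial's input vector (as passed to the forward pass).
#' @param outcome The trial outcome from [agrel_trial()] (or an equivalent
#'   list with `gamma`, `winner`, `f_delta`).
#' @param beta Learning rate.
#' @return A new `agrel_weights` object; the inputs are not modified.
#' @export
single_trial_update <- function(weights, x, outcome, beta = 0.01) {
  if (length(x) != nrow(weights$v) - 1L) .stopf("input/weight shape mismatch")
  s <- outcome$winner
  f <- outcome$f_delta
  gf <- outcome$gamma
  if (length(gf) != nrow(weights$w)) .stopf("outcome/weight shape mismatch")
  w_s_pre <- weights$w[, s]
  w_new <- weights$w
  w_new[, s] <- w_s_pre + beta * f * gf
  gh <- gf[-1]
  attn <- gh * (1 - gh) * w_s_pre[-1]
  v_new <- weights$v + beta * f * outer(c(1, x), attn)
  structure(list(v = v_new, w = w_new), class = "agrel_weights")
}

#' @export
print.agrel_weights <- function(x, ...) {
  cat(sprintf("<agrel_weights> %d inputs -> %d hidden -> %d outputs\n",
              nrow(x$v) - 1L, ncol(x$v), ncol(x$w)))
  invisible(x)
}
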