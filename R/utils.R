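# Internal numerical helpers shared by the R reference implementations and
# the package front-ends.  The C++ core mirrors these exactly (same clamps,
# same stable softmax, same winner-sampling rule) so R- and C++-computed
# traces agree.

# sigmoid clamped away from 0/1 so the attention factor gamma*(1-gamma) and
# log-space quantities stay finite
.sigmoid <- function(h) {
  pmin(pmax(1 / (1 + exp(-h)), 1e-12), 1 - 1e-12)
}

# numerically stable softmax for a single drive vector
.softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

# row-wise stable softmax for a matrix of drives
.softmax_rows <- function(A) {
  E <- exp(A - apply(A, 1L, max))
  E / rowSums(E)
}

# forward pass for a whole trial matrix; returns the class-probability matrix
.probs_matrix <- function(weights, X) {
  Xf <- cbind(1, X)
  G <- .sigmoid(Xf %*% weights$v)
  A <- cbind(1, G) %*% weights$w
  .softmax_rows(A)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded helpers compose without disturbing the
#' caller's stream.  With `seed = NULL` the expression simply uses the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a named sub-stream seed from a master seed
#'
#' One master seed fans out to independent, reproducible sub-streams (network
#' init, action sampling, simulator, bootstrap, ...) by hashing the stream
#' name into an offset.  The result is always a valid 32-bit seed.
#'
#' @param master Integer master seed.
#' @param stream Character stream name.
#' @param index Optional integer (e.g. repeat number) folded into the seed.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer((abs(master) %% 2147483629 + h + 97 * abs(index)) %% 2147483629 + 1)
}

# short content hash used to stamp artifacts with their configuration
.config_hash <- function(x) {
  substr(rlang::hash(x), 1L, 12L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    .stopf("`%s` must be a single integer >= %s", name, format(min))
  }
  invisible(TRUE)
}

# validate integer class labels in 1..n_classes
.check_labels <- function(y, n_classes) {
  if (any(!is.finite(y)) || any(y != round(y)) || any(y < 1) || any(y > n_classes)) {
    .stopf("labels must be integers in 1..%d", n_classes)
  }
  invisible(TRUE)
}
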