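#' RBF-kernel classifier specification for the static/retrained baselines
#'
#' Grid-searched support-vector classifier with a radial-basis-function
#' kernel.  The default grids are the standard coarse search recommended for
#' this kernel: cost `2^-5 .. 2^15` and kernel width `2^-15 .. 2^3`, both in
#' steps of 2 in the exponent, with 3-fold cross-validation.
#'
#' @param C_grid Penalty (cost) candidates.
#' @param gamma_grid Kernel-width candidates.
#' @param cv_folds Cross-validation folds for the grid search (default 3).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        cv_folds = 3) {
  if (length(C_grid) < 1L || length(gamma_grid) < 1L) {
    .stopf("parameter grids must be non-empty")
  }
  .check_count(cv_folds, "cv_folds", min = 2)
  structure(
    list(C_grid = C_grid, gamma_grid = gamma_grid,
         cv_folds = as.integer(cv_folds)),
    class = "kernel_spec"
  )
}

#' Train the static (frozen) kernel decoder
#'
#' Grid-searches `(C, gamma)` by cross-validated accuracy on the historical
#' data (fold assignment drawn from the current RNG stream), refits at the
#' best pair (ties resolved in grid order), and freezes the predictor.
#' Consumes raw, unprojected features.
#'
#' @param X Historical trials x features matrix.
#' @param y Integer labels (at least two classes present).
#' @param spec A [kernel_spec()].
#' @return An object of class `static_decoder` with the fitted model and the
#'   selected parameters; predict with [predict.static_decoder()].
#' @export
train_static <- function(X, y, spec = kernel_spec()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  lev <- sort(unique(y))
  if (length(lev) < 2L) .stopf("single-class input")
  n <- nrow(X)
  folds <- sample(rep_len(seq_len(spec$cv_folds), n))
  grid <- expand.grid(cost = spec$C_grid, gamma = spec$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  yf <- factor(y, levels = lev)
  cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
    acc <- vapply(seq_len(spec$cv_folds), function(fold) {
      tr <- folds != fold
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = grid$cost[i], gamma = grid$gamma[i],
                        scale = FALSE)
      mean(predict(fit, X[!tr, , drop = FALSE]) == yf[!tr])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_acc) # first maximum: deterministic tie-break
  fit <- e1071::svm(X, yf, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE)
  structure(
    list(model = fit, cost = grid$cost[best], gamma = grid$gamma[best],
         cv_accuracy = cv_acc[best], levels = lev, folds = folds,
         grid = cbind(grid, cv_accuracy = cv_acc)),
    class = "static_decoder"
  )
}

#' Predict with a static kernel decoder
#'
#' @param object A `static_decoder`.
#' @param newdata Trials x features matrix.
#' @param ... Unused.
#' @return Integer predicted labels.
#' @export
predict.static_decoder <- function(object, newdata, ...) {
  as.integer(as.character(predict(object$model, as.matrix(newdata))))
}

#' Retrained-decoder protocol on the current day
#'
#' The upper-reference calibration: for each repeat a seeded random
#' two-thirds/one-third train/test split of the *current* session is drawn,
#' the kernel decoder is grid-searched and fitted on the train split, and
#' test-split accuracy is recorded.
#'
#' @param session A `session_dataset` (or list with `features`, `labels`).
#' @param split_fraction Fraction of trials used for training (default 2/3).
#' @param repeats Number of random splits (default 50).
#' @param spec A [kernel_spec()].
#' @param seed Optional master seed.
#' @return An object of class `retrained_result`: list with per-repeat
#'   `accuracies`, `n_train`, `n_test`, per-repeat `test_indices` and
#'   `predictions`, and the labels.
#' @export
retrained_protocol <- function(session, split_fraction = 2 / 3, repeats = 50,
                               spec = kernel_spec(), seed = NULL) {
  X <- as.matrix(session$features)
  y <- as.integer(session$labels)
  n <- nrow(X)
  n_train <- round(n * split_fraction)
  if (n_train < 2L || n_train >= n) .stopf("session too small for the split")
  with_seed(seed, {
    acc <- numeric(repeats)
    test_idx <- vector("list", repeats)
    preds <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      fit <- train_static(X[tr, , drop = FALSE], y[tr], spec)
      p <- predict(fit, X[te, , drop = FALSE])
      acc[r] <- mean(p == y[te])
      test_idx[[r]] <- te
      preds[[r]] <- p
    }
    structure(
      list(accuracies = acc, n_train = n_train, n_test = n - n_train,
           test_indices = test_idx, predictions = preds, labels = y),
      class = "retrained_result"
    )
  })
}

#' Build a decoder-pipeline descriptor by method name
#'
#' Returns pure configuration distinguishing the five compared calibration
#' schemes:
#'
#' * `static` -- frozen RBF-kernel classifier trained on historical data;
#' * `retrained` -- kernel classifier retrained on current-day splits;
#' * `nagrel` -- AGREL network trained once on raw historical features, run
#'   without any online adaptation;
#' * `agrel` -- AGREL trained without the confidence gate and adapted online
#'   with a full buffer of all tested samples and no gate (one update pass
#'   per trial);
#' * `tmagrl` -- PDA projection, gated training, and gated mini-batch
#'   adaptation with buffer size `J`.
#'
#' @param name One of `"static"`, `"retrained"`, `"nagrel"`, `"agrel"`,
#'   `"tmagrl"`.
#' @param J Mini-batch size for `tmagrl` (default 30).
#' @return An object of class `decoder_method`.
#' @export
make_method <- function(name, J = 30) {
  name <- match.arg(name, c("static", "retrained", "nagrel", "agrel", "tmagrl"))
  desc <- switch(name,
    static = list(kind = "svm", retrain = FALSE),
    retrained = list(kind = "svm", retrain = TRUE),
    nagrel = list(kind = "rl", use_pda = FALSE, train_gate = TRUE,
                  adapt = FALSE, J = J, online_gate = TRUE),
    agrel = list(kind = "rl", use_pda = FALSE, train_gate = FALSE,
                 adapt = TRUE, J = Inf, online_gate = FALSE),
    tmagrl = list(kind = "rl", use_pda = TRUE, train_gate = TRUE,
                  adapt = TRUE, J = J, online_gate = TRUE)
  )
  structure(c(list(name = name), desc), class = "decoder_method")
}
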