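#' Classification accuracy
#'
#' @param predictions Predicted labels.
#' @param labels True labels of the same length (non-empty).
#' @return Fraction of exact matches.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0L) .stopf("empty input")
  if (length(predictions) != length(labels)) .stopf("length mismatch")
  mean(predictions == labels)
}

#' Confusion matrix of decoding results
#'
#' @param predictions Predicted labels in `1..n_classes`.
#' @param labels True labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return An `n_classes x n_classes` count matrix, actual classes in rows
#'   and predicted classes in columns.
#' @export
confusion_matrix <- function(predictions, labels, n_classes) {
  .check_count(n_classes, "n_classes")
  .check_labels(predictions, n_classes)
  .check_labels(labels, n_classes)
  cm <- table(
    factor(labels, levels = seq_len(n_classes)),
    factor(predictions, levels = seq_len(n_classes))
  )
  m <- matrix(as.integer(cm), n_classes, n_classes)
  dimnames(m) <- list(actual = seq_len(n_classes),
                      predicted = seq_len(n_classes))
  m
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the per-repeat values with replacement `n_boot` times and takes
#' percentiles of the resampled means.
#'
#' @param values Numeric vector of per-repeat accuracies (>= 2 values).
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional seed.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 1000, seed = NULL) {
  if (length(values) < 2L) .stopf("need at least 2 values")
  if (level <= 0 || level >= 1) .stopf("`level` must be in (0, 1)")
  with_seed(seed, {
    m <- matrix(sample(values, length(values) * n_boot, replace = TRUE),
                nrow = n_boot)
    means <- rowMeans(m)
    unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

# run one RL-method repeat on a fixed train/test pair; returns predictions
.run_rl_once <- function(method, train_session, test_session, training,
                         adaptation) {
  model <- train_initial(
    train_session$features, train_session$labels,
    training = training, use_pda = method$use_pda, gate = method$train_gate
  )
  cfg <- adaptation_config(
    J = method$J, k = adaptation$k,
    convergence_fraction = adaptation$convergence_fraction,
    max_update_epochs = adaptation$max_update_epochs,
    beta = adaptation$beta, gate = method$online_gate
  )
  run_online(model, test_session, cfg, adapt = method$adapt)
}

# aggregate one experiment cell into an eval_report
.make_report <- function(method_name, metadata, accuracies, confusion,
                         seeds, n_boot = 1000, ci_seed = NULL) {
  ci <- if (length(accuracies) >= 2L) {
    bootstrap_ci(accuracies, n_boot = n_boot, seed = ci_seed)
  } else {
    rep(accuracies, 2L)
  }
  structure(
    list(method = method_name, metadata = metadata, accuracies = accuracies,
         mean_accuracy = mean(accuracies), ci_low = ci[1], ci_high = ci[2],
         confusion = confusion, n_repeats = length(accuracies),
         seeds = seeds),
    class = "eval_report"
  )
}

#' Run a benchmark experiment over a session series
#'
#' Drives the three standard designs over a multi-day series:
#'
#' * `previous_day`: for every consecutive day pair, train on day `t - 1`
#'   and test on day `t`;
#' * `day_separation`: the last day is the test set and every earlier day
#'   serves in turn as the training day (separation = day gap);
#' * `batch_sweep`: a fixed pair (last two days) decoded by TMAGRL at batch
#'   sizes `J = 1, 30, 60, ...` up to the session size.
#'
#' Train/test data are fixed per cell; repeats re-draw the network
#' initialisation and all action-sampling streams from per-repeat seeds
#' derived from the master seed.  The `retrained` method ignores the
#' training day and re-splits the test day per repeat; `static` is
#' deterministic given its fold assignment and runs once per cell.
#'
#' @param series A `session_series` (list of `session_dataset`).
#' @param design `"previous_day"`, `"day_separation"`, or `"batch_sweep"`.
#' @param methods Character vector of method names (see [make_method()]);
#'   `batch_sweep` always uses `tmagrl`.
#' @param repeats Repeats per cell (default 50).
#' @param seed Master seed.
#' @param training A [training_config()].
#' @param adaptation An [adaptation_config()] (provides `k`, inner-loop
#'   settings, and the default `J`).
#' @param spec A [kernel_spec()] for the SVM-based methods.
#' @param batch_sizes Optional explicit `J` values for `batch_sweep`.
#' @return A list of `eval_report` objects (class `experiment_result`);
#'   see [as.data.frame.experiment_result()] for a tabular summary.
#' @export
run_experiment <- function(series,
                           design = c("previous_day", "day_separation",
                                      "batch_sweep"),
                           methods = c("static", "nagrel", "retrained",
                                       "agrel", "tmagrl"),
                           repeats = 50, seed = 1,
                           training = training_config(),
                           adaptation = adaptation_config(),
                           spec = kernel_spec(), batch_sizes = NULL) {
  design <- match.arg(design)
  n_days <- length(series)
  cells <- switch(design,
    previous_day = {
      if (n_days < 2L) .stopf("need >= 2 days for previous_day")
      lapply(seq.int(2L, n_days), function(t) {
        list(train = t - 1L, test = t, J = NULL)
      })
    },
    day_separation = {
      if (n_days < 2L) .stopf("need >= 2 days for day_separation")
      lapply(seq_len(n_days - 1L), function(t) {
        list(train = t, test = n_days, J = NULL)
      })
    },
    batch_sweep = {
      if (n_days < 2L) .stopf("need >= 2 days for batch_sweep")
      n_test <- nrow(series[[n_days]]$features)
      Js <- if (is.null(batch_sizes)) {
        c(1, if (n_test >= 30) seq(30, n_test, by = 30) else n_test)
      } else {
        batch_sizes
      }
      lapply(Js, function(J) {
        list(train = n_days - 1L, test = n_days, J = J)
      })
    }
  )
  if (design == "batch_sweep") methods <- "tmagrl"

  reports <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    train_session <- series[[cell$train]]
    test_session <- series[[cell$test]]
    n_classes <- max(test_session$labels)
    meta <- list(design = design, train_day = cell$train,
                 test_day = cell$test,
                 separation = cell$test - cell$train, J = cell$J)
    for (mname in methods) {
      method <- make_method(mname, J = if (is.null(cell$J)) adaptation$J
                                       else cell$J)
      cell_seed <- derive_seed(seed, paste(design, mname), ci)
      if (method$kind == "svm" && !method$retrain) {
        fit <- with_seed(cell_seed,
                         train_static(train_session$features,
                                      train_session$labels, spec))
        p <- predict(fit, test_session$features)
        acc <- accuracy(p, test_session$labels)
        conf <- confusion_matrix(p, test_session$labels, n_classes)
        reports[[length(reports) + 1L]] <-
          .make_report(mname, meta, acc, conf, cell_seed)
      } else if (method$kind == "svm") {
        rp <- retrained_protocol(test_session, repeats = repeats,
                                 spec = spec, seed = cell_seed)
        conf <- matrix(0L, n_classes, n_classes)
        for (r in seq_len(repeats)) {
          conf <- conf + confusion_matrix(
            rp$predictions[[r]], rp$labels[rp$test_indices[[r]]], n_classes
          )
        }
        reports[[length(reports) + 1L]] <-
          .make_report(mname, meta, rp$accuracies, conf, cell_seed,
                       ci_seed = derive_seed(cell_seed, "boot"))
      } else {
        acc <- numeric(repeats)
        conf <- matrix(0L, n_classes, n_classes)
        rep_seeds <- vapply(seq_len(repeats), function(r) {
          derive_seed(cell_seed, "repeat", r)
        }, integer(1))
        for (r in seq_len(repeats)) {
          res <- with_seed(rep_seeds[r],
                           .run_rl_once(method, train_session, test_session,
                                        training, adaptation))
          acc[r] <- res$accuracy
          conf <- conf + confusion_matrix(res$trace$predicted,
                                          res$trace$true, n_classes)
        }
        reports[[length(reports) + 1L]] <-
          .make_report(mname, meta, acc, conf, rep_seeds,
                       ci_seed = derive_seed(cell_seed, "boot"))
      }
    }
  }
  structure(reports, class = "experiment_result")
}

#' Summarise an experiment result as a data frame
#'
#' @param x An `experiment_result` from [run_experiment()].
#' @param ... Unused.
#' @return A data frame with one row per (cell, method): design, train/test
#'   days, separation, batch size, repeats, mean accuracy, and the 95%
#'   bootstrap interval.
#' @export
as.data.frame.experiment_result <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(
      design = r$metadata$design, method = r$method,
      train_day = r$metadata$train_day, test_day = r$metadata$test_day,
      separation = r$metadata$separation,
      J = if (is.null(r$metadata$J)) NA_real_ else r$metadata$J,
      n_repeats = r$n_repeats, mean_accuracy = r$mean_accuracy,
      ci_low = r$ci_low, ci_high = r$ci_high
    )
  }))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s (%s, train day %s -> test day %s): %.3f [%.3f, %.3f], %d repeats\n",
    x$method, x$metadata$design, x$metadata$train_day, x$metadata$test_day,
    x$mean_accuracy, x$ci_low, x$ci_high, x$n_repeats
  ))
  invisible(x)
}

#' @export
print.experiment_result <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}
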