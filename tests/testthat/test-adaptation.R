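test_that("the buffer is exactly FIFO with oldest-first eviction", {
  b <- mb_buffer(3)
  expect_length(b, 0)
  b <- mb_push(b, c(1, 1), 1L)
  expect_length(b, 1)
  for (i in 2:3) b <- mb_push(b, c(i, i), i %% 3 + 1L)
  expect_length(b, 3)
  b <- mb_push(b, c(4, 4), 2L)
  expect_length(b, 3)
  expect_equal(b$X[, 1], c(2, 3, 4)) # first sample evicted, order kept
  # before the buffer fills, all tested samples participate
  b2 <- mb_buffer(30)
  for (i in 1:7) b2 <- mb_push(b2, rnorm(2), 1L)
  expect_length(b2, 7)
  expect_error(mb_push(b2, rnorm(5), 1L), "dimension")
})

test_that("a one-sample pass reduces to the single-trial rule", {
  set.seed(40)
  for (rep in 1:10) {
    W <- random_weights(3, 5, 3)
    x <- rnorm(3)
    y <- sample(1:3, 1)
    b <- mb_push(mb_buffer(10), x, y)
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    got <- mb_update_pass(W, b, beta = 0.01)
    set.seed(seed)
    out <- agrel_trial(W, x, y)
    want <- single_trial_update(W, x, out, beta = 0.01)
    expect_equal(got$v, want$v, tolerance = 1e-12)
    expect_equal(got$w, want$w, tolerance = 1e-12)
  }
})

test_that("mini-batch pass matches the summed oracle and is linear in duplicates", {
  set.seed(41)
  W <- random_weights(4, 3, 3)
  X <- matrix(rnorm(5 * 4), 5, 4)
  y <- c(1L, 2L, 3L, 1L, 2L)
  b <- mb_buffer(10)
  for (i in 1:5) b <- mb_push(b, X[i, ], y[i])
  # reproduce the pass with known winners by replaying the RNG
  seed <- 4711
  set.seed(seed)
  got <- mb_update_pass(W, b, beta = 0.02)
  set.seed(seed)
  u <- runif(5)
  winners <- integer(5)
  f <- numeric(5)
  for (i in 1:5) {
    fw <- oracle_forward(W$v, W$w, X[i, ])
    winners[i] <- min(findInterval(u[i], cumsum(fw$p)) + 1L, 3L)
    delta <- if (winners[i] == y[i]) 1 - fw$p[winners[i]] else -1
    f[i] <- if (delta < 0) -1 else min(delta, 0.99) / (1 - min(delta, 0.99))
  }
  want <- oracle_mb_update(W$v, W$w, X, winners, f, beta = 0.02)
  expect_equal(got$v, want$v, tolerance = 1e-12)
  expect_equal(got$w, want$w, tolerance = 1e-12)

  # duplicating a sample doubles its contribution (fixed winners)
  one <- oracle_mb_update(W$v, W$w, X[c(1, 2), ], c(2L, 3L), c(0.5, -1), 0.02)
  two <- oracle_mb_update(W$v, W$w, X[c(1, 1, 2), ], c(2L, 2L, 3L),
                          c(0.5, 0.5, -1), 0.02)
  expect_equal(two$w - W$w - 2 * (one$w - W$w) +
                 oracle_mb_update(W$v, W$w, X[2, , drop = FALSE], 3L, -1,
                                  0.02)$w - W$w,
               matrix(0, 4, 3), tolerance = 1e-12)

  # confidently-correct buffer with delta = 0 everywhere gives a zero update
  # (f = 0 for every sample forces both sums to vanish)
  wantz <- oracle_mb_update(W$v, W$w, X, c(1L, 2L, 3L, 1L, 2L), rep(0, 5), 0.02)
  expect_identical(wantz$v, W$v)
  expect_identical(wantz$w, W$w)
})

test_that("gated trials leave the model bit-identical", {
  set.seed(42)
  toy <- toy_clusters(15)
  m <- train_initial(toy$X, toy$y, use_pda = FALSE,
                     training = training_config(seed = 42))
  # pick a trial the trained model classifies with high confidence
  cf <- confidence(m$weights, toy$X, toy$y)
  i <- which(cf > 0.9)[1]
  b <- mb_buffer(30)
  res <- test_and_adapt(m, b, toy$X[i, ], toy$y[i])
  expect_true(res$gated)
  expect_equal(res$update_passes, 0L)
  expect_identical(res$model$weights$v, m$weights$v)
  expect_identical(res$model$weights$w, m$weights$w)
  expect_length(res$buffer, 1) # gated samples still enter the buffer
})

test_that("un-gated adaptation raises the buffer's confident fraction", {
  set.seed(43)
  hits <- replicate(100, {
    W <- random_weights(2, 6, 3)
    toy <- toy_clusters(4, sep = 4)
    b <- mb_buffer(12)
    for (i in sample(nrow(toy$X))) b <- mb_push(b, toy$X[i, ], toy$y[i])
    pre <- mean(confidence(W, b$X, b$y) > 0.9)
    cfg <- adaptation_config(J = 12, max_update_epochs = 20)
    res <- test_and_adapt(W, b, toy$X[1, ], toy$y[1], cfg)
    post <- mean(confidence(res$model, res$buffer$X, res$buffer$y) > 0.9)
    post >= pre
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the compiled online loop matches the R reference path", {
  set.seed(44)
  toy <- toy_clusters(10)
  m <- train_initial(toy$X, toy$y, use_pda = FALSE,
                     training = training_config(max_epochs = 30, seed = 44))
  sess <- list(features = toy$X, labels = toy$y)
  cfg <- adaptation_config(J = 7, max_update_epochs = 5)
  res_cpp <- with_seed(7, run_online(m, sess, cfg, adapt = TRUE))
  # R reference: stream trials through test_and_adapt with the same RNG
  res_r <- with_seed(7, {
    model <- m
    b <- mb_buffer(7)
    trace <- lapply(seq_len(nrow(toy$X)), function(t) {
      out <- test_and_adapt(model, b, toy$X[t, ], toy$y[t], cfg)
      model <<- out$model
      b <<- out$buffer
      c(out$predicted, out$gated, out$update_passes)
    })
    list(trace = do.call(rbind, trace), weights = model$weights)
  })
  expect_equal(res_cpp$trace$predicted, res_r$trace[, 1])
  expect_equal(as.integer(res_cpp$trace$gated), res_r$trace[, 2])
  expect_equal(res_cpp$trace$update_passes, res_r$trace[, 3])
  expect_equal(res_cpp$model$weights$v, res_r$weights$v, tolerance = 1e-10)
  expect_equal(res_cpp$model$weights$w, res_r$weights$w, tolerance = 1e-10)
})

test_that("without adaptation the weights never move", {
  set.seed(45)
  series <- simulate_series(scaled_sim(2))
  m <- train_initial(series[[1]]$features, series[[1]]$labels,
                     training = training_config(seed = 45))
  res <- run_online(m, series[[2]], adapt = FALSE)
  expect_identical(res$model$weights$v, m$weights$v)
  expect_identical(res$model$weights$w, m$weights$w)
  expect_true(all(res$trace$update_passes == 0))
})

test_that("per-trial causality: truncated runs reproduce the prefix", {
  set.seed(46)
  series <- simulate_series(scaled_sim(3))
  m <- train_initial(series[[1]]$features, series[[1]]$labels,
                     training = training_config(seed = 46))
  full <- with_seed(11, run_online(m, series[[2]], adaptation_config(J = 10)))
  half_sess <- list(features = series[[2]]$features[1:40, ],
                    labels = series[[2]]$labels[1:40])
  half <- with_seed(11, run_online(m, half_sess, adaptation_config(J = 10)))
  expect_identical(half$trace, full$trace[1:40, ])
})

test_that("adaptation is neutral on stationary data and helps after drift", {
  accs <- sapply(1:8, function(s) {
    series <- simulate_series(scaled_sim(s, drift_sigma = 0, dropout_prob = 0))
    set.seed(300 + s)
    m <- train_initial(series[[1]]$features, series[[1]]$labels)
    a1 <- run_online(m, series[[2]], adapt = TRUE)$accuracy
    a0 <- run_online(m, series[[2]], adapt = FALSE)$accuracy
    c(a1, a0)
  })
  expect_lt(abs(mean(accs[1, ]) - mean(accs[2, ])), 0.03)

  accs_d <- sapply(1:8, function(s) {
    series <- simulate_series(scaled_sim(s, drift_sigma = 0.3))
    set.seed(400 + s)
    m <- train_initial(series[[1]]$features, series[[1]]$labels)
    a1 <- run_online(m, series[[2]], adapt = TRUE)$accuracy
    a0 <- run_online(m, series[[2]], adapt = FALSE)$accuracy
    c(a1, a0)
  })
  expect_gte(mean(accs_d[1, ]), mean(accs_d[2, ]) + 0.05)
})
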