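test_that("tuning model draws respect the configured structure", {
  cfg <- sim_config(n_channels = 80, trials_per_class_per_day = 10,
                    n_days = 1, seed = 1)
  set.seed(1)
  tm <- make_tuning_model(cfg)
  expect_equal(dim(tm$rates), c(80, 3, 6))
  expect_true(all(tm$rates >= 0))
  expect_true(all(tm$active_mask))
  # 80 channels x 6 bins -> the 480-element feature layout downstream
  sess <- simulate_session(tm, cfg)
  expect_equal(ncol(sess$features), 480)

  # no modulation: all classes share identical rates per channel
  cfg0 <- sim_config(n_channels = 12, trials_per_class_per_day = 5,
                     tuning_gain = 0, n_days = 1, seed = 1)
  set.seed(2)
  tm0 <- make_tuning_model(cfg0)
  expect_equal(tm0$rates[, 1, ], tm0$rates[, 2, ])
  expect_equal(tm0$rates[, 1, ], tm0$rates[, 3, ])

  # determinism given the stream seed
  set.seed(7)
  a <- make_tuning_model(cfg)
  set.seed(7)
  b <- make_tuning_model(cfg)
  expect_identical(a, b)

  expect_error(sim_config(n_classes = 1), "n_classes")
})

test_that("drift is a random walk on log-gains with channel dropout", {
  cfg_id <- sim_config(n_channels = 10, trials_per_class_per_day = 5,
                       drift_sigma = 0, dropout_prob = 0, n_days = 1, seed = 1)
  set.seed(3)
  tm <- make_tuning_model(cfg_id)
  expect_equal(drift_tuning(tm, cfg_id)$rates, tm$rates)

  cfg_drop <- sim_config(n_channels = 10, trials_per_class_per_day = 5,
                         drift_sigma = 0, dropout_prob = 1, n_days = 1, seed = 1)
  dropped <- drift_tuning(tm, cfg_drop)
  expect_true(all(dropped$rates == 0))
  expect_false(any(dropped$active_mask))

  # mean |log gain| after k steps grows like sqrt(k) (Monte Carlo, 2000
  # channels): ratio of step-16 to step-4 divergence should be close to 2
  cfg_mc <- sim_config(n_channels = 2000, trials_per_class_per_day = 5,
                       drift_sigma = 0.1, dropout_prob = 0, n_days = 1, seed = 1)
  set.seed(4)
  tm_mc <- make_tuning_model(cfg_mc)
  cur <- tm_mc
  div <- numeric(16)
  for (k in 1:16) {
    cur <- drift_tuning(cur, cfg_mc)
    div[k] <- mean(abs(log(cur$rates[, 1, 1] / tm_mc$rates[, 1, 1])))
  }
  expect_equal(div[16] / div[4], 2, tolerance = 0.15)
  # and the absolute scale matches the folded-normal mean sigma*sqrt(2k/pi)
  expect_equal(div[9], 0.1 * sqrt(2 * 9 / pi), tolerance = 0.1)
})

test_that("session counts are Poisson with balanced shuffled labels", {
  cfg <- sim_config(n_channels = 4, trials_per_class_per_day = 30,
                    n_days = 1, seed = 5)
  set.seed(5)
  tm <- make_tuning_model(cfg)
  sess <- simulate_session(tm, cfg)
  expect_true(all(sess$features >= 0))
  expect_true(is.integer(sess$features))
  expect_equal(as.vector(table(sess$labels)), rep(30, 3))

  # empirical mean count matches rate * bin_width within 3 standard errors
  cfg_big <- sim_config(n_channels = 1, trials_per_class_per_day = 10000,
                        n_classes = 2, tuning_gain = 0, n_days = 1, seed = 6,
                        base_rate_range = c(20, 20))
  set.seed(6)
  tm_big <- make_tuning_model(cfg_big)
  sess_big <- simulate_session(tm_big, cfg_big)
  lam <- 20 * 0.05
  se <- sqrt(lam / nrow(sess_big$features))
  expect_lt(abs(mean(sess_big$features[, 1]) - lam), 3 * se)

  # all-zero rates give an all-zero feature matrix
  tm0 <- tm
  tm0$rates[] <- 0
  set.seed(7)
  expect_true(all(simulate_session(tm0, cfg)$features == 0))

  # monkey-M-like day size: 210 trials/class x 3 classes = 630 trials
  cfg_m <- sim_config(n_channels = 4, trials_per_class_per_day = 210,
                      n_days = 1, seed = 8)
  set.seed(8)
  expect_equal(nrow(simulate_session(make_tuning_model(cfg_m), cfg_m)$features),
               630)
})

test_that("series generation is deterministic and monkey-B-like sizes work", {
  cfg <- sim_config(n_channels = 66, trials_per_class_per_day = 120,
                    n_days = 4, seed = 42)
  s1 <- simulate_series(cfg)
  s2 <- simulate_series(cfg)
  expect_identical(s1, s2)
  expect_length(s1, 4)
  for (d in 1:4) {
    expect_equal(dim(s1[[d]]$features), c(360, 396))
    expect_equal(s1[[d]]$day_index, d)
  }
  expect_equal(s1[[2]]$name, "S1D2")
})

test_that("a fixed day-1 readout degrades across drifting days", {
  # mean accuracy of a frozen nearest-centroid readout is non-increasing
  # across days 2..5; the per-day decline at the default drift is a couple
  # of points, so 40 seeds are averaged to resolve the trend
  accs <- sapply(1:40, function(s) {
    series <- simulate_series(sim_config(
      n_channels = 20, trials_per_class_per_day = 30, n_days = 5, seed = s
    ))
    ctr <- centroid_fit(series[[1]]$features, series[[1]]$labels)
    sapply(2:5, function(d) {
      mean(centroid_predict(ctr, series[[d]]$features) == series[[d]]$labels)
    })
  })
  m <- rowMeans(accs)
  expect_true(all(diff(m) <= 0.01)) # non-increasing up to simulation noise
  expect_lt(m[4], m[1])
})

test_that("separability is monotone in tuning gain", {
  acc_at_gain <- function(g) {
    mean(sapply(1:10, function(s) {
      series <- simulate_series(sim_config(
        n_channels = 15, trials_per_class_per_day = 40, n_days = 1,
        tuning_gain = g, seed = s
      ))
      X <- series[[1]]$features
      y <- series[[1]]$labels
      half <- seq_len(nrow(X)) %% 2 == 0
      ctr <- centroid_fit(X[half, ], y[half])
      mean(centroid_predict(ctr, X[!half, ]) == y[!half])
    }))
  }
  a_low <- acc_at_gain(0.3)
  a_mid <- acc_at_gain(0.8)
  a_high <- acc_at_gain(1.5)
  expect_gte(a_mid, a_low - 0.02)
  expect_gte(a_high, a_mid - 0.02)
})

test_that("between-day disparity of class-conditional means grows with separation", {
  disparity <- function(series, d) {
    m0 <- centroid_fit(series[[1]]$features, series[[1]]$labels)
    md <- centroid_fit(series[[d]]$features, series[[d]]$labels)
    mean(abs(md - m0))
  }
  disp <- sapply(1:10, function(s) {
    series <- simulate_series(sim_config(
      n_channels = 20, trials_per_class_per_day = 40, n_days = 5, seed = s
    ))
    sapply(2:5, function(d) disparity(series, d))
  })
  m <- rowMeans(disp)
  expect_true(all(diff(m) > -0.01)) # non-decreasing on average
})
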