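cfg <- test_config()

test_that("lag expansion has the documented shape and shift structure", {
  lags <- decoder_lags(cfg)
  expect_identical(lags, 0:16)                      # 0-250 ms at 64 Hz
  set.seed(1)
  x <- matrix(rnorm(15 * 100), 15)
  d <- build_lagged_design(x, lags)
  expect_equal(dim(d), c(15 * 17, 100))
  # lag 0 only: the design is the input
  expect_equal(build_lagged_design(x, 0L)[, ], x, ignore_attr = TRUE)
  # explicit tiny case: [a b c] with lags {0, 1} -> rows [a b c], [b c 0]
  d2 <- build_lagged_design(matrix(c(5, 7, 11), 1), 0:1)
  expect_equal(d2[1, ], c(5, 7, 11))
  expect_equal(d2[2, ], c(7, 11, 0))
  expect_error(build_lagged_design(x, 0:200), "exceeds")
})

test_that("ridge solution matches the brute-force normal-equation oracle", {
  set.seed(123)
  for (rep in 1:25) {
    n_ch <- sample(1:5, 1)
    n_lag <- sample(1:6, 1)
    n_t <- sample(50:300, 1)
    lambda <- sample(c(0.1, 1, 10, 100), 1)
    x <- matrix(rnorm(n_ch * n_t), n_ch)
    s <- rnorm(n_t)
    dec <- fit_ridge_decoder(build_lagged_design(x, 0:(n_lag - 1)), s, lambda)
    w_oracle <- oracle_ridge_weights(x, s, 0:(n_lag - 1), lambda)
    rel <- max(abs(as.vector(dec$weights) - w_oracle)) /
      max(abs(w_oracle))
    expect_lt(rel, 1e-8)
  }
})

test_that("ridge recovers an exact linear map and shrinks with lambda", {
  set.seed(2)
  x <- matrix(rnorm(3 * 200), 3)
  d <- build_lagged_design(x, 0L)
  dec <- fit_ridge_decoder(d, x[1, ], lambda = 0)
  expect_equal(as.vector(dec$weights), c(1, 0, 0), tolerance = 1e-8)
  norms <- vapply(c(0, 1, 100, 1e4, 1e9), function(l) {
    sqrt(sum(fit_ridge_decoder(d, x[1, ], l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))                 # monotone shrinkage
  expect_lt(norms[length(norms)], 1e-6)             # lambda -> inf kills weights
  # rank-deficient + lambda 0 is a helpful error
  xdup <- rbind(x[1, ], x[1, ])
  expect_error(fit_ridge_decoder(build_lagged_design(xdup, 0L), x[1, ], 0),
               "lambda > 0")
})

test_that("reconstruction is linear in the decoder and follows the lag convention", {
  set.seed(3)
  x <- matrix(rnorm(2 * 150), 2)
  d <- build_lagged_design(x, 0:2)
  mk <- function(w) aadkit:::new_decoder(w, 1, 0:2, 64, c("a", "b"))
  w1 <- matrix(rnorm(6), 3); w2 <- matrix(rnorm(6), 3)
  lhs <- reconstruct_envelope(mk(2 * w1 + 3 * w2), d)$values
  rhs <- 2 * reconstruct_envelope(mk(w1), d)$values +
    3 * reconstruct_envelope(mk(w2), d)$values
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  # zero decoder -> zero envelope
  expect_equal(reconstruct_envelope(mk(matrix(0, 3, 2)), d)$values,
               rep(0, 150))
  # unit weight at (lag 1, channel 1) picks out the shifted channel
  w <- matrix(0, 3, 2); w[2, 1] <- 1
  out <- reconstruct_envelope(mk(w), d)$values
  expect_equal(out, c(x[1, 2:150], 0))
  # training solution reconstructs its own noiseless training envelope
  s <- rnorm(150)
  dtrain <- build_lagged_design(rbind(s, rnorm(150)), 0L)
  dec <- fit_ridge_decoder(dtrain, s, 1e-8)
  expect_gt(cor(reconstruct_envelope(dec, dtrain)$values, s), 0.99)
})

test_that("trial classification uses a strict inequality with conservative ties", {
  expect_true(classify_trial(0.20, 0.05, 1))
  expect_false(classify_trial(0.05, 0.20, 1))
  expect_true(classify_trial(0.05, 0.20, 2))
  expect_false(classify_trial(0.2, 0.2, 1))         # tie -> incorrect
  expect_false(classify_trial(NaN, -0.5, 1))        # NaN treated as -Inf
  expect_true(classify_trial(0.1, NaN, 1))
})

test_that("LOOCV is perfect on noise-free data and invariant to speaker relabeling", {
  model <- default_model(cfg, noise_sd = 0, gain_unattended = 0.25)
  ds <- make_tiny_dataset(6, 30, model, cfg, seed = 4)
  res <- loocv_evaluate(ds, cfg)
  expect_equal(res$accuracy, 100)
  expect_equal(res$n_trials, 6)
  expect_true(all(res$trials$r_attended > res$trials$r_unattended))
  # relabeling speakers 1<->2 together with their envelopes changes nothing
  res2 <- loocv_evaluate(relabel_speakers(ds), cfg)
  expect_equal(res2$accuracy, res$accuracy)
  expect_equal(res2$trials$r_attended, res$trials$r_attended, tolerance = 1e-12)
  # averaging identical decoders returns the same decoder: with all trials
  # identical, each fold's averaged decoder must equal a single-trial fit
  one <- ds[1, ]
  dup <- dplyr::bind_rows(one, one, one)
  dup$trial_id <- c("a", "b", "c")
  res3 <- loocv_evaluate(dup, cfg)
  expect_equal(res3$trials$r1, rep(res3$trials$r1[1], 3), tolerance = 1e-10)
})

test_that("LOOCV rejects switching trials and too-small sets", {
  model <- default_model(cfg, noise_sd = 0)
  ds <- make_tiny_dataset(2, 30, model, cfg,
                          kinds = c("fixed", "switching"), switch_time_s = 15,
                          seed = 5)
  expect_error(loocv_evaluate(ds, cfg), "switching")
  expect_error(loocv_evaluate(ds[1, ], cfg), "at least 2")
})

test_that("noise-free LOOCV stays perfect across gain ratios and seeds", {
  for (seed in 1:3) {
    gain_un <- sample(c(0.1, 0.25, 0.5), 1)
    model <- default_model(cfg, seed = 20 + seed, noise_sd = 0,
                           gain_unattended = gain_un)
    ds <- make_tiny_dataset(4, 20, model, cfg, seed = seed)
    expect_equal(loocv_evaluate(ds, cfg)$accuracy, 100)
  }
})

test_that("decoder tidiers expose weights and fit summaries", {
  set.seed(10)
  x <- matrix(rnorm(2 * 100), 2)
  dec <- fit_ridge_decoder(build_lagged_design(x, 0:3), rnorm(100), 10)
  td <- tidy(dec)
  expect_equal(nrow(td), 8)
  expect_named(td, c("lag", "lag_ms", "channel", "weight"))
  gl <- glance(dec)
  expect_equal(gl$n_lags, 4)
  expect_equal(gl$lambda, 10)
})
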