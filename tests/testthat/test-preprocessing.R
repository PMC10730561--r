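cfg <- test_config()

test_that("envelope extraction recovers a known modulator", {
  set.seed(21)
  fs <- 8000
  t <- (0:(60 * fs - 1)) / fs
  mod <- 1 + 0.9 * sin(2 * pi * 2 * t)          # 2 Hz amplitude modulation
  wave <- mod * rnorm(length(t))
  env <- extract_envelope(wave, fs, cfg)
  expect_true(env$standardized)
  expect_equal(env$fs, 64)
  expect_length(env$values, 60 * 64)            # round(duration * 64)
  # oracle: push the known modulator through the same five-step chain
  ref <- zscore(resample_signal(bandpass(mod, fs, 0.5, 8), fs, 64))
  expect_gt(cor(env$values, ref), 0.95)
})

test_that("envelope extraction rejects degenerate input", {
  expect_error(extract_envelope(numeric(8000), 8000, cfg), "degenerate|zero")
  expect_error(extract_envelope(rnorm(100), 8000, cfg), "1 s")
})

test_that("common-average re-referencing zeroes the channel mean and is offset-invariant", {
  tr <- eeg_trial(matrix(c(1, 2), 2, 50), fs = 10, channel_labels = c("Fz", "Cz"))
  car <- rereference_common_average(tr)
  expect_equal(unique(car$data[1, ]), -0.5)
  expect_equal(unique(car$data[2, ]), 0.5)
  expect_equal(car$reference, "common-average")
  expect_error(rereference_common_average(car), "already")

  set.seed(1)
  m <- matrix(rnorm(15 * 100), 15)
  t1 <- rereference_common_average(eeg_trial(m, 125, aad_montage()))
  expect_lt(max(abs(colMeans(t1$data))), 1e-10)
  # adding a common offset to all channels changes nothing
  t2 <- rereference_common_average(eeg_trial(m + 3.7, 125, aad_montage()))
  expect_lt(max(abs(t1$data - t2$data)), 1e-10)
  # already centered data is unchanged
  t3 <- rereference_common_average(eeg_trial(t1$data, 125, aad_montage()))
  expect_lt(max(abs(t3$data - t1$data)), 1e-12)
  expect_error(rereference_common_average(eeg_trial(m[1, , drop = FALSE], 125, "Fz")),
               "2 channels")
})

test_that("band-pass keeps in-band tones, rejects out-of-band ones and DC", {
  fs <- 125
  t <- (0:(fs * 20 - 1)) / fs
  mid <- (fs * 5):(fs * 15)                # avoid filter edge transients
  in_band <- sin(2 * pi * 4 * t)
  y <- bandpass(in_band, fs, 0.5, 8)
  expect_gt(max(abs(y[mid])), 0.95)
  out_band <- sin(2 * pi * 30 * t)
  y2 <- bandpass(out_band, fs, 0.5, 8)
  expect_lt(max(abs(y2[mid])), 0.1)        # >= 90 % attenuation at 30 Hz
  y3 <- bandpass(rnorm(length(t)) + 10, fs, 0.5, 8)
  expect_lt(abs(mean(y3[mid])), 0.05)      # DC removed (steady state)
  expect_error(bandpass(t, fs, 8, 0.5), "band edges")
  expect_error(bandpass(t, fs, 0.5, 80), "band edges")
})

test_that("resampling has the right length, preserves constants and sinusoids", {
  expect_length(resample_signal(rnorm(7500), 125, 64), 3840)
  cst <- resample_signal(rep(2.5, 1000), 125, 64)
  expect_lt(max(abs(cst - 2.5)), 1e-9)
  t <- (0:7499) / 125
  y <- resample_signal(sin(2 * pi * 2 * t), 125, 64)
  ref <- sin(2 * pi * 2 * (0:(length(y) - 1)) / 64)
  mid <- 200:3600
  expect_lt(max(abs(y[mid] - ref[mid])), 0.02)  # amplitude within 2 %
  expect_error(resample_signal(rnorm(100), 64, 125), "downsample")
})

test_that("z-scoring uses population SD and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z <- zscore(rnorm(100))
  expect_lt(max(abs(zscore(z) - z)), 1e-9)      # idempotent
  expect_error(zscore(rep(1, 50)), "zero variance")
})

test_that("whole-trial preprocessing composes the chain in the canonical order", {
  set.seed(5)
  tr <- eeg_trial(matrix(rnorm(15 * 7500), 15), 125, aad_montage())
  out <- preprocess_eeg(tr, cfg)
  expect_equal(dim(out$data), c(15, 3840))
  expect_equal(out$fs, 64)
  expect_lt(max(abs(rowMeans(out$data))), 1e-9)
  sds <- apply(out$data, 1, function(r) sqrt(mean((r - mean(r))^2)))
  expect_lt(max(abs(sds - 1)), 1e-9)
  expect_identical(out$channel_labels, aad_montage())  # order preserved

  # the op order matters: z-scoring before filtering gives different output
  swapped <- t(apply(tr$data, 1, function(r) {
    resample_signal(bandpass(zscore(r), 125, 0.5, 8), 125, 64)
  }))
  expect_gt(max(abs(swapped - out$data)), 1e-3)
})

test_that("repeated passes of the identity-rate chain contract", {
  # the band-pass is an order-3 Butterworth, not a brick wall: re-filtering
  # re-attenuates content near the band edges, so the chain is not exactly
  # idempotent. It must however be contractive: each additional pass
  # changes the signal less than the one before.
  set.seed(6)
  cfg64 <- aad_config(fs_acq = 64)
  tr <- eeg_trial(matrix(rnorm(15 * 64 * 60), 15), 64, aad_montage())
  p1 <- preprocess_eeg(tr, cfg64)
  p2 <- preprocess_eeg(eeg_trial(p1$data, 64, p1$channel_labels), cfg64)
  p3 <- preprocess_eeg(eeg_trial(p2$data, 64, p2$channel_labels), cfg64)
  rel <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  r12 <- rel(p2$data, p1$data)
  r23 <- rel(p3$data, p2$data)
  expect_lt(r23, r12)
  expect_lt(r23, 0.1)
  # the already-filtered signal is highly correlated with its re-filtered self
  expect_gt(cor(as.vector(p2$data), as.vector(p1$data)), 0.98)
})

test_that("snippet preprocessing is causal, deterministic and sized W x fs_proc", {
  set.seed(9)
  buf <- matrix(rnorm(15 * round(15 * 125)), 15)
  envs <- list(generate_envelope(60, 64, seed = 1, speaker_id = 1),
               generate_envelope(60, 64, seed = 2, speaker_id = 2))
  s1 <- preprocess_snippet(buf, envs, cfg, i = 1)
  s2 <- preprocess_snippet(buf, envs, cfg, i = 1)
  expect_identical(s1, s2)                           # determinism
  expect_equal(dim(s1$eeg), c(15, 960))              # 15 s x 64 Hz
  expect_length(s1$segments[[1]], 960)
  expect_equal(s1$window_end_s, 15)
  # each segment is re-z-scored
  seg <- s1$segments[[2]]
  expect_lt(abs(mean(seg)), 1e-9)
  expect_lt(abs(sqrt(mean((seg - mean(seg))^2)) - 1), 1e-9)
  # underrun and degenerate channels are rejected
  expect_error(preprocess_snippet(buf[, 1:100], envs, cfg, 1), "underrun")
  # identical channels become all-zero after common-average referencing
  same <- matrix(rep(rnorm(round(15 * 125)), each = 2), 2)
  expect_error(preprocess_snippet(same, envs, cfg, 1), "zero variance|degenerate")
})
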