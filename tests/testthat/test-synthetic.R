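cfg <- test_config()

test_that("generated envelopes are sized, standardized, reproducible and independent", {
  e <- generate_envelope(60, 64, seed = 1)
  expect_length(e$values, 3840)
  expect_true(e$standardized)
  expect_lt(abs(mean(e$values)), 1e-9)
  # same seed -> identical; different seeds -> near-zero correlation
  e2 <- generate_envelope(60, 64, seed = 1)
  expect_identical(e$values, e2$values)
  cors <- vapply(2:9, function(s) {
    cor(e$values, generate_envelope(60, 64, seed = s)$values)
  }, numeric(1))
  expect_lt(max(abs(cors)), 0.1)
  # seeded generation leaves the caller's RNG stream untouched
  set.seed(99); a <- rnorm(3)
  set.seed(99); invisible(generate_envelope(5, 64, seed = 7)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("generated TRFs have the documented shape and unit peaks", {
  k <- generate_trf(n_channels = 15, fs = 64, seed = 2)
  expect_equal(dim(k), c(17, 15))
  expect_equal(apply(abs(k), 2, max), rep(1, 15))
  expect_true(all(colSums(k^2) > 0))
  expect_identical(k, generate_trf(n_channels = 15, fs = 64, seed = 2))
})

test_that("noise-free forward-model trials are decodable by construction", {
  model <- default_model(cfg, noise_sd = 0, gain_unattended = 0)
  ds <- make_tiny_dataset(4, 60, model, cfg, seed = 51)
  # parameter recovery: with zero unattended gain and no noise the decoder
  # reconstructs the attended envelope almost perfectly on held-out trials;
  # the residual comes from the pipeline itself (the trial passes through
  # the band-pass twice, which re-attenuates content near the band edges)
  res <- loocv_evaluate(ds, cfg)
  expect_gt(min(res$trials$r_attended), 0.98)
  expect_equal(res$accuracy, 100)
})

test_that("equal gains with identical kernels give chance-level decoding", {
  trf <- generate_trf(fs = cfg$fs_proc, seed = 61)
  model <- forward_model(trf, trf, gain_attended = 1, gain_unattended = 1,
                         noise_sd = 0.5, lapse_s = 0)
  correct <- integer(0)
  for (seed in 1:6) {
    ds <- make_tiny_dataset(6, 20, model, cfg, seed = 100 + seed)
    correct <- c(correct, loocv_evaluate(ds, cfg)$trials$correct)
  }
  n <- length(correct)                      # 36 Bernoulli(0.5) draws
  band <- stats::qbinom(c(0.025, 0.975), n, 0.5)
  expect_gte(sum(correct), band[1])
  expect_lte(sum(correct), band[2])
})

test_that("switching trials encode the attention lapse in the EEG", {
  trf <- generate_trf(fs = cfg$fs_proc, seed = 71)
  md_fix <- trial_metadata("f", 1, "left", "fixed", duration_s = 60)
  md_sw <- trial_metadata("s", 1, "left", "switching", switch_time_s = 30,
                          duration_s = 60)
  env1 <- generate_envelope(60, 64, seed = 1, speaker_id = 1)
  env2 <- generate_envelope(60, 64, seed = 2, speaker_id = 2)
  model0 <- forward_model(trf, trf * 0.5, gain_attended = 1,
                          gain_unattended = 0.25, noise_sd = 0, lapse_s = 8)
  set.seed(1); fix <- simulate_trial(env1, env2, model0, md_fix, fs_acq = 125)
  set.seed(1); sw <- simulate_trial(env1, env2, model0, md_sw, fs_acq = 125)
  expect_equal(dim(fix$data), c(15, 7500))
  # identical before the switch, different during the lapse
  pre <- 1:(25 * 125); lapse <- (31 * 125):(37 * 125)
  expect_lt(max(abs(fix$data[, pre] - sw$data[, pre])), 1e-8)
  expect_gt(max(abs(fix$data[, lapse] - sw$data[, lapse])), 0.01)
  # a zero-length lapse makes the switching trial identical to the fixed one
  model_l0 <- forward_model(trf, trf * 0.5, gain_attended = 1,
                            gain_unattended = 0.25, noise_sd = 0, lapse_s = 0)
  set.seed(1); sw0 <- simulate_trial(env1, env2, model_l0, md_sw, fs_acq = 125)
  expect_equal(sw0$data, fix$data, tolerance = 1e-12)
})

test_that("the generated dataset reproduces the experimental design", {
  ds <- generate_dataset(cfg, seed = 5, n_trials = 30, n_switching = 4)
  expect_equal(nrow(ds), 30)
  expect_equal(sum(ds$kind == "switching"), 4)
  expect_equal(sum(ds$attended_side_initial == "left"), 15)
  expect_equal(sum(ds$attended_side_initial == "right"), 15)
  sw <- ds$switch_time_s[ds$kind == "switching"]
  expect_true(all(sw >= 27 & sw <= 33))
  # switching trials sit in the test portion (after the 14 training trials)
  expect_true(all(which(ds$kind == "switching") > 14))
  expect_true(all(vapply(ds$eeg, function(e) e$fs, numeric(1)) == 125))
  expect_true(all(vapply(ds$env1, function(e) e$standardized, logical(1))))
})

test_that("dataset generation is reproducible and the manifest round-trips", {
  ds1 <- generate_dataset(cfg, seed = 9, n_trials = 6, n_switching = 1,
                          duration_s = 20, n_train = 2,
                          switch_range_s = c(15, 18))
  ds2 <- generate_dataset(cfg, seed = 9, n_trials = 6, n_switching = 1,
                          duration_s = 20, n_train = 2,
                          switch_range_s = c(15, 18))
  expect_identical(ds1$eeg[[3]]$data, ds2$eeg[[3]]$data)
  expect_identical(ds1$switch_time_s, ds2$switch_time_s)
  dir <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(ds1, dir)
  write_dataset(ds2, dir2)
  expect_identical(readLines(file.path(dir, "manifest.tsv")),
                   readLines(file.path(dir2, "manifest.tsv")))
  back <- read_dataset(dir)
  expect_equal(nrow(back), 6)
  expect_lt(max(abs(back$eeg[[1]]$data - ds1$eeg[[1]]$data)), 1e-12)
  expect_equal(back$kind, ds1$kind)
})

test_that("decoding accuracy degrades as forward-model noise grows", {
  # the hard regime: identical kernels for both speakers, so discrimination
  # rests entirely on the 10 % gain margin, with broadband (white) noise
  # and short trials. With distinct per-speaker kernels the linear decoder
  # projects the competing stream out and stays at ceiling far longer.
  trf <- generate_trf(fs = cfg$fs_proc, seed = 81)
  acc <- vapply(c(0, 32, 128), function(ns) {
    model <- forward_model(trf, trf, gain_attended = 1, gain_unattended = 0.9,
                           noise_sd = ns, noise_spectrum = "white")
    mean(vapply(1:3, function(s) {
      loocv_evaluate(make_tiny_dataset(8, 16, model, cfg, seed = 300 + s),
                     cfg)$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_equal(acc[1], 100)
  expect_lt(acc[2], acc[1])
  expect_lt(acc[3], acc[2])
})
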