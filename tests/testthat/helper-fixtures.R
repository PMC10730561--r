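# Shared fixtures and independent oracles, all built in code at test time.

test_config <- function(...) aad_config(...)

# --- independent brute-force oracles (element-by-element loops; kept
# deliberately naive and separate from the package's vectorized path) ----

oracle_lagged <- function(x, lags) {
  n_ch <- nrow(x); n_t <- ncol(x); n_lag <- length(lags)
  out <- matrix(0, n_lag * n_ch, n_t)
  for (ch in seq_len(n_ch)) {
    for (j in seq_len(n_lag)) {
      for (t in seq_len(n_t)) {
        tt <- t + lags[j]
        out[(ch - 1) * n_lag + j, t] <- if (tt <= n_t) x[ch, tt] else 0
      }
    }
  }
  out
}

oracle_ridge_weights <- function(x, s, lags, lambda) {
  m <- oracle_lagged(x, lags)
  MASS::ginv(m %*% t(m) + lambda * diag(nrow(m))) %*% (m %*% s)
}

# --- synthetic building blocks -------------------------------------------

# a tiny dataset tibble in the generate_dataset() shape, built from an
# explicit forward model so tests can control gains and kernels exactly
make_tiny_dataset <- function(n_trials, duration_s, model, cfg,
                              kinds = rep("fixed", n_trials),
                              switch_time_s = 30, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_trials), function(k) {
    md <- trial_metadata(
      trial_id = sprintf("t%02d", k), attended_speaker = 1,
      attended_side_initial = if (k %% 2) "left" else "right",
      kind = kinds[k],
      switch_time_s = if (kinds[k] == "switching") switch_time_s else NA_real_,
      duration_s = duration_s
    )
    env1 <- generate_envelope(duration_s, cfg$fs_proc, speaker_id = 1)
    env2 <- generate_envelope(duration_s, cfg$fs_proc, speaker_id = 2)
    eeg <- simulate_trial(env1, env2, model, md, fs_acq = cfg$fs_acq)
    dplyr::mutate(md, eeg = list(eeg), env1 = list(env1), env2 = list(env2))
  })
  dplyr::bind_rows(rows)
}

default_model <- function(cfg, seed = 11, ...) {
  trf1 <- generate_trf(fs = cfg$fs_proc, seed = seed)
  trf2 <- generate_trf(fs = cfg$fs_proc, seed = seed + 1)
  forward_model(trf1, trf2, ...)
}

# swap the two speakers everywhere (envelopes + attended label); the EEG
# is untouched, so any decoding result must be invariant
relabel_speakers <- function(dataset) {
  tmp <- dataset$env1
  dataset$env1 <- dataset$env2
  dataset$env2 <- tmp
  dataset$attended_speaker <- 3L - dataset$attended_speaker
  dataset
}

# hand-built correlation trace: windows ending 15..duration s, with the
# post-switch correctness pattern prescribed by `post_correct`
make_trace <- function(post_correct, switch_time_s = 30, duration_s = 60,
                       attended = 1L, pre_correct = TRUE) {
  ends <- seq(15, duration_s)
  is_post <- ends > switch_time_s
  stopifnot(sum(is_post) == length(post_correct))
  ok <- rep(pre_correct, length(ends))
  ok[is_post] <- post_correct
  r_att <- ifelse(ok, 0.3, -0.1)
  r_un <- ifelse(ok, -0.1, 0.3)
  tibble::tibble(
    trial_id = "tx",
    window = seq_along(ends),
    window_end_s = ends,
    r1_raw = if (attended == 1) r_att else r_un,
    r2_raw = if (attended == 1) r_un else r_att,
    r1_ema = NA_real_, r2_ema = NA_real_,
    decision = NA_integer_,
    correct = ok,
    attended_speaker = attended,
    kind = "switching",
    switch_time_s = switch_time_s
  )
}
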