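# Simulated real-time decoding: a W-second buffer advanced every M seconds,
# each snippet preprocessed causally, reconstructed with the averaged
# snippet-wise decoder, and the two envelope correlations smoothed with an
# exponential moving average before the per-window decision.

#' Enumerate sliding windows over a trial
#'
#' Window i ends at `buffer_s + (i - 1) * step_s` seconds: the first window
#' is the first completely filled buffer, subsequent windows advance by the
#' step. A 60-s trial with a 15-s window and 1-s step yields 46 windows
#' ending at 15, 16, ..., 60 s.
#'
#' @param duration_s Trial duration T in seconds (must be at least
#'   `buffer_s`).
#' @param window_s Window width W in seconds.
#' @param step_s Step M in seconds.
#' @param buffer_s Initial buffer length; defaults to `window_s`.
#' @return A tibble with columns `window` (1-based index) and `end_time_s`.
#' @export
#' @examples
#' nrow(enumerate_windows(60, 15, 1))  # 46
enumerate_windows <- function(duration_s, window_s = 15, step_s = 1,
                              buffer_s = window_s) {
  if (buffer_s < window_s) abort("buffer_s must be at least window_s")
  if (duration_s < buffer_s) {
    abort(sprintf("trial of %g s is shorter than the %g-s buffer: no full window",
                  duration_s, buffer_s))
  }
  k <- floor((duration_s - buffer_s) / step_s + 1e-9) + 1
  tibble::tibble(window = seq_len(k),
                 end_time_s = buffer_s + (seq_len(k) - 1) * step_s)
}

#' Fit a snippet-wise decoder
#'
#' Identical ridge mathematics to [fit_ridge_decoder()], applied to one
#' W-second snippet: \eqn{D_i = (R_i R_i^\top + \lambda I)^{-1} R_i S_i^\top}.
#'
#' @param snippet An `aad_snippet` from [preprocess_snippet()].
#' @param attended_segment Numeric vector: the attended speaker's
#'   (re-z-scored) envelope segment for the same window.
#' @param lambda Ridge parameter.
#' @param lag_samples Integer sample lags (see [decoder_lags()]).
#' @return An `aad_decoder`.
#' @export
fit_snippet_decoder <- function(snippet, attended_segment, lambda = 10,
                                lag_samples) {
  stopifnot(inherits(snippet, "aad_snippet"))
  design <- build_lagged_design(snippet$eeg, lag_samples)
  fit_ridge_decoder(design, attended_segment, lambda)
}

#' Train the real-time decoder
#'
#' Builds the streaming decoder \eqn{\bar D} as the elementwise mean of all
#' snippet-wise decoders over every (trial, window) pair of the training
#' set, all weighted equally. With 14 one-minute training trials at
#' W = 15 s, M = 1 s this averages 14 x 46 = 644 snippet decoders.
#'
#' @param trials Training tibble in the [generate_dataset()] shape
#'   (list-columns `eeg`, `env1`, `env2`; column `attended_speaker`).
#' @param config An [aad_config()].
#' @return An `aad_decoder` whose `provenance` field counts the averaged
#'   snippet decoders.
#' @export
train_realtime_decoder <- function(trials, config = aad_config()) {
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) < 1) abort("empty training set")
  lags <- decoder_lags(config)
  w_sum <- NULL
  count <- 0L
  labels <- NULL
  for (k in seq_len(nrow(trials))) {
    raw <- trials$eeg[[k]]
    envs <- list(trials$env1[[k]], trials$env2[[k]])
    att <- trials$attended_speaker[k]
    wins <- enumerate_windows(duration_s(raw), config$window_s,
                              config$step_s, config$buffer_s)
    for (i in wins$window) {
      end_s <- wins$end_time_s[i]
      cols <- (round((end_s - config$window_s) * raw$fs) + 1):round(end_s * raw$fs)
      snip <- preprocess_snippet(raw$data[, cols, drop = FALSE], envs, config, i)
      dec <- fit_snippet_decoder(snip, snip$segments[[att]],
                                 config$lambda_reg, lags)
      w_sum <- if (is.null(w_sum)) dec$weights else w_sum + dec$weights
      count <- count + 1L
      labels <- raw$channel_labels
    }
  }
  new_decoder(w_sum / count, lambda = config$lambda_reg, lag_samples = lags,
              fs = config$fs_proc, channel_labels = labels,
              provenance = count)
}

#' Exponential moving average of a correlation sequence
#'
#' The recursion \eqn{\hat r_1 = r_1};
#' \eqn{\hat r_i = \alpha r_i + (1 - \alpha)\hat r_{i-1}} for \eqn{i > 1}.
#' Recent windows are weighted more heavily; \eqn{\alpha = 1} is the
#' identity. The state is reset at every trial start (the caller applies
#' this per trial). Non-finite entries propagate the previous state
#' unchanged so a single degenerate window does not poison the trace.
#'
#' @param raw Numeric vector of per-window correlations.
#' @param alpha Smoothing weight in (0, 1].
#' @return Numeric vector, same length.
#' @export
#' @examples
#' apply_ema(c(1, 0, 0), 0.1)  # 1, 0.9, 0.81
apply_ema <- function(raw, alpha = 0.1) {
  if (length(raw) < 1) abort("need at least one value")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("alpha must lie in (0, 1]")
  }
  out <- numeric(length(raw))
  out[1] <- raw[1]
  for (i in seq_along(raw)[-1]) {
    out[i] <- if (is.finite(raw[i])) {
      if (is.finite(out[i - 1])) alpha * raw[i] + (1 - alpha) * out[i - 1] else raw[i]
    } else {
      out[i - 1]
    }
  }
  out
}

#' Stream-decode a test trial
#'
#' Simulates the real-time loop on one trial: for every sliding window the
#' raw EEG buffer is preprocessed causally ([preprocess_snippet()]), the
#' envelope is reconstructed with the trained decoder, Pearson correlations
#' with both speakers' envelope segments are computed, the two correlation
#' sequences are EMA-smoothed independently, and the window is assigned to
#' the speaker with the larger smoothed correlation (ties and degenerate
#' windows count as incorrect). Raw correlations are kept alongside for the
#' temporal-sensitivity analysis, which must not use the EMA.
#'
#' @param trial Raw [eeg_trial()] at `config$fs_acq`.
#' @param env1,env2 Standardized full-trial [envelope()]s at
#'   `config$fs_proc` for speakers 1 and 2.
#' @param decoder Trained `aad_decoder` (see [train_realtime_decoder()]).
#' @param config An [aad_config()].
#' @param metadata One-row metadata (see [trial_metadata()]); supplies the
#'   attended speaker, trial kind and switch time carried on the trace.
#' @return An `aad_trace` tibble: `trial_id`, `window`, `window_end_s`,
#'   `r1_raw`, `r2_raw`, `r1_ema`, `r2_ema`, `decision`, `correct`, plus
#'   `attended_speaker`, `kind`, `switch_time_s`; attribute `ema_alpha`.
#' @export
stream_decode <- function(trial, env1, env2, decoder, config = aad_config(),
                          metadata) {
  stopifnot(inherits(trial, "eeg_trial"), inherits(decoder, "aad_decoder"))
  md <- as.list(tibble::as_tibble(metadata)[1, ])
  att <- md$attended_speaker
  wins <- enumerate_windows(duration_s(trial), config$window_s,
                            config$step_s, config$buffer_s)
  envs <- list(env1, env2)
  r1 <- r2 <- rep(NA_real_, nrow(wins))
  for (i in wins$window) {
    end_s <- wins$end_time_s[i]
    cols <- (round((end_s - config$window_s) * trial$fs) + 1):round(end_s * trial$fs)
    ri <- tryCatch({
      snip <- preprocess_snippet(trial$data[, cols, drop = FALSE], envs, config, i)
      design <- build_lagged_design(snip$eeg, decoder$lag_samples)
      shat <- reconstruct_envelope(decoder, design)$values
      c(safe_cor(shat, snip$segments[[1]]), safe_cor(shat, snip$segments[[2]]))
    }, error = function(e) c(NA_real_, NA_real_))
    r1[i] <- ri[1]; r2[i] <- ri[2]
  }
  e1 <- apply_ema(r1, config$ema_alpha)
  e2 <- apply_ema(r2, config$ema_alpha)
  e_att <- if (att == 1) e1 else e2
  e_un <- if (att == 1) e2 else e1
  correct <- is.finite(e_att) & is.finite(e_un) & (e_att > e_un)
  correct[is.na(correct)] <- FALSE
  decision <- ifelse(correct, att, 3L - as.integer(att))
  out <- tibble::tibble(
    trial_id = md$trial_id %||% trial$trial_id,
    window = wins$window,
    window_end_s = wins$end_time_s,
    r1_raw = r1, r2_raw = r2,
    r1_ema = e1, r2_ema = e2,
    decision = as.integer(decision),
    correct = correct,
    attended_speaker = as.integer(att),
    kind = md$kind %||% "fixed",
    switch_time_s = as.numeric(md$switch_time_s %||% NA_real_)
  )
  attr(out, "ema_alpha") <- config$ema_alpha
  class(out) <- c("aad_trace", class(out))
  out
}

#' Pooled window accuracy of real-time decoding
#'
#' Percentage of correctly classified windows pooled over all trials, with
#' the split by trial kind (location-fixed vs location-switching) reported
#' alongside.
#'
#' @param traces One `aad_trace` or several bound together
#'   (e.g. `dplyr::bind_rows(...)`).
#' @return A tibble with rows `all`, `fixed`, `switching` (where present)
#'   and columns `kind`, `accuracy`, `n_windows`, `n_trials`.
#' @export
window_accuracy <- function(traces) {
  traces <- tibble::as_tibble(traces)
  if (nrow(traces) == 0) abort("no windows to score")
  one <- function(df, label) {
    tibble::tibble(kind = label,
                   accuracy = 100 * mean(df$correct),
                   n_windows = nrow(df),
                   n_trials = dplyr::n_distinct(df$trial_id))
  }
  out <- one(traces, "all")
  for (k in intersect(c("fixed", "switching"), unique(traces$kind))) {
    out <- dplyr::bind_rows(out, one(traces[traces$kind == k, ], k))
  }
  out
}
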