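# Forward-model synthetic data. Attention is modeled purely as a gain
# difference: every channel is a temporal-response-function (TRF)
# convolution of the attended envelope plus a weaker convolution of the
# unattended one plus noise. This is the minimal generative model the
# backward decoder can invert, and it reproduces the two-speaker
# experimental design (30 one-minute trials, 26 location-fixed and 4
# location-switching with switch times jittered between 27 and 33 s,
# sides balanced 15/15) so the whole pipeline runs without hardware.

#' Generate a speech-like envelope
#'
#' Band-limited random amplitude envelope: white noise is rectified
#' (non-negative, like a true amplitude envelope), band-pass filtered so
#' the 0.5--8 Hz modulation band dominates, then z-scored.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz (the processing rate).
#' @param seed Optional integer; when given the caller's RNG state is left
#'   untouched.
#' @param speaker_id Identifier stored on the envelope.
#' @param passband_hz Modulation band, default `c(0.5, 8)`.
#' @return A standardized [envelope()].
#' @export
generate_envelope <- function(duration_s, fs = 64, seed = NULL,
                              speaker_id = NA, passband_hz = c(0.5, 8)) {
  if (duration_s <= 0) abort("duration_s must be positive")
  n <- round(duration_s * fs)
  with_seed(seed, {
    raw <- abs(rnorm(n))
    bp <- bandpass(raw, fs, passband_hz[1], passband_hz[2])
    envelope(zscore(bp), fs = fs, standardized = TRUE, speaker_id = speaker_id)
  })
}

#' Generate temporal response functions
#'
#' One smooth kernel per channel: a damped oscillation with channel-specific
#' frequency (2--6 Hz), decay (50--150 ms) and phase, normalized to unit
#' peak. These play the role of the cortical impulse response linking the
#' speech envelope to each EEG channel.
#'
#' @param n_channels Number of channels (default 15, the AAD montage).
#' @param lag_span_ms Kernel support in ms, default `c(0, 250)`.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @return A lags x channels matrix (17 x 15 at the defaults).
#' @export
generate_trf <- function(n_channels = 15, lag_span_ms = c(0, 250),
                         fs = 64, seed = NULL) {
  n_lag <- floor(lag_span_ms[2] / 1000 * fs) - floor(lag_span_ms[1] / 1000 * fs) + 1
  t <- (floor(lag_span_ms[1] / 1000 * fs) + seq_len(n_lag) - 1) / fs
  with_seed(seed, {
    k <- vapply(seq_len(n_channels), function(ch) {
      f <- runif(1, 2, 6)
      tau <- runif(1, 0.05, 0.15)
      phi <- runif(1, 0, 2 * pi)
      v <- exp(-t / tau) * sin(2 * pi * f * t + phi)
      if (max(abs(v)) < 1e-3) v <- v + exp(-t / tau)  # avoid a near-null kernel
      v / max(abs(v))
    }, numeric(n_lag))
    matrix(k, nrow = n_lag, ncol = n_channels)
  })
}

#' Forward model specification
#'
#' @param trf_attended,trf_unattended Lags x channels kernels (see
#'   [generate_trf()]); the unattended kernel defaults to the attended one.
#' @param gain_attended,gain_unattended Non-negative stream gains. The gain
#'   ratio is what makes attention decodable; equal gains give
#'   chance-level decoding by symmetry.
#' @param noise_sd Noise standard deviation relative to the unit-variance
#'   convolved streams.
#' @param noise_spectrum `"one-over-f"` (EEG-like) or `"white"`.
#' @param lapse_s Attention-lapse length L in seconds for switching trials:
#'   from the switch time the effective gains are swapped for L seconds,
#'   modeling the transient disruption while the listener reorients (the
#'   attended speaker itself never changes).
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(trf_attended, trf_unattended = NULL,
                          gain_attended = 1, gain_unattended = 0.5,
                          noise_sd = 1,
                          noise_spectrum = c("one-over-f", "white"),
                          lapse_s = 8) {
  noise_spectrum <- match.arg(noise_spectrum)
  if (gain_attended < 0 || gain_unattended < 0) abort("gains must be non-negative")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  structure(
    list(trf_attended = trf_attended,
         trf_unattended = trf_unattended %||% trf_attended,
         gain_attended = gain_attended, gain_unattended = gain_unattended,
         noise_sd = noise_sd, noise_spectrum = noise_spectrum,
         lapse_s = lapse_s),
    class = "forward_model"
  )
}

# causal convolution of an envelope with a kernel: y[t] = sum_j k[j] x[t-j+1]
conv_causal <- function(x, k) {
  y <- stats::filter(x, k, method = "convolution", sides = 1)
  y[is.na(y)] <- 0
  as.numeric(y)
}

noise_channel <- function(n, sd, spectrum) {
  if (sd == 0) return(numeric(n))
  w <- rnorm(n)
  if (spectrum == "white") return(sd * w)
  # shape |X(f)| ~ f^(-1/2) => power ~ 1/f
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric over positive/negative bins
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE) / n)
  sd * x / stats::sd(x)
}

#' Simulate one EEG trial from the forward model
#'
#' Each channel is synthesized at the processing rate as
#' `gain_att * (trf (*) attended env) + gain_unatt * (trf' (*) unattended
#' env) + noise`, then upsampled to the acquisition rate (125 Hz) so the
#' full resampling path of the pipeline is exercised. For switching trials
#' the effective gains are swapped during the attention lapse
#' `[switch_time_s, switch_time_s + lapse_s)`.
#'
#' @param env1,env2 [envelope()]s for speakers 1 and 2 at the processing
#'   rate, covering the trial duration.
#' @param model A [forward_model()].
#' @param metadata One-row metadata from [trial_metadata()].
#' @param fs_acq Acquisition rate, default 125 Hz.
#' @param channel_labels Labels, default [aad_montage()] truncated/recycled
#'   to the kernel's channel count.
#' @return A raw [eeg_trial()] at `fs_acq`.
#' @export
simulate_trial <- function(env1, env2, model, metadata, fs_acq = 125,
                           channel_labels = NULL) {
  stopifnot(inherits(model, "forward_model"))
  md <- as.list(tibble::as_tibble(metadata)[1, ])
  fs <- env1$fs
  n <- round(md$duration_s * fs)
  if (length(env1$values) < n || length(env2$values) < n) {
    abort("envelopes are shorter than the trial duration")
  }
  att <- md$attended_speaker
  e_att <- (if (att == 1) env1 else env2)$values[seq_len(n)]
  e_un <- (if (att == 1) env2 else env1)$values[seq_len(n)]
  # during the attention lapse of a switching trial the *roles* of the two
  # streams swap: the competing speaker transiently receives the attended
  # processing (kernel and gain) while the listener reorients. With shared
  # kernels this reduces to a pure gain swap.
  lapse <- rep(FALSE, n)
  if (identical(md$kind, "switching") && model$lapse_s > 0) {
    i0 <- floor(md$switch_time_s * fs) + 1
    i1 <- min(n, floor((md$switch_time_s + model$lapse_s) * fs))
    if (i0 <= i1) lapse[i0:i1] <- TRUE
  }
  n_ch <- ncol(model$trf_attended)
  if (is.null(channel_labels)) {
    channel_labels <- rep_len(aad_channels, n_ch)
  }
  data <- matrix(0, n_ch, round(md$duration_s * fs_acq))
  r <- ratio_int(fs_acq, fs)
  for (ch in seq_len(n_ch)) {
    normal <- model$gain_attended * conv_causal(e_att, model$trf_attended[, ch]) +
      model$gain_unattended * conv_causal(e_un, model$trf_unattended[, ch])
    sig <- if (any(lapse)) {
      swapped <- model$gain_attended * conv_causal(e_un, model$trf_attended[, ch]) +
        model$gain_unattended * conv_causal(e_att, model$trf_unattended[, ch])
      ifelse(lapse, swapped, normal)
    } else {
      normal
    }
    sig <- sig + noise_channel(n, model$noise_sd, model$noise_spectrum)
    data[ch, ] <- resample_rational(sig, r[1], r[2])
  }
  eeg_trial(data, fs = fs_acq, channel_labels = channel_labels,
            reference = "recording-reference", trial_id = md$trial_id)
}

#' Generate a complete synthetic AAD dataset
#'
#' Reproduces the two-speaker experimental design: `n_trials` one-minute
#' trials, `n_switching` of them location-switching with switch times drawn
#' uniformly in 27--33 s (always in the test portion, i.e. after the first
#' 14 trials at the default sizes), presentation sides balanced
#' left/right, the same speaker (speaker 1) attended throughout.
#'
#' @param config An [aad_config()].
#' @param seed Integer seed; the dataset is fully reproducible from
#'   (config, seed, generator arguments).
#' @param n_trials Total trial count (default 30).
#' @param n_switching Location-switching trial count (default 4).
#' @param duration_s Trial duration (default 60 s).
#' @param n_train Number of initial fixed trials reserved for real-time
#'   training (switching trials are placed after them).
#' @param gain_attended,gain_unattended,noise_sd,noise_spectrum,lapse_s
#'   Forward-model parameters, see [forward_model()].
#' @param switch_range_s Uniform jitter range of switch times.
#' @return An `aad_dataset`: a tibble with one row per trial, metadata
#'   columns (`trial_id`, `kind`, `attended_speaker`,
#'   `attended_side_initial`, `switch_time_s`, `duration_s`) and
#'   list-columns `eeg`, `env1`, `env2`; attributes `config`, `seed`,
#'   `model`.
#' @export
generate_dataset <- function(config = aad_config(), seed = 1,
                             n_trials = 30, n_switching = 4,
                             duration_s = 60, n_train = 14,
                             gain_attended = 1, gain_unattended = 0.5,
                             noise_sd = 1,
                             noise_spectrum = c("one-over-f", "white"),
                             lapse_s = 8,
                             switch_range_s = c(27, 33)) {
  noise_spectrum <- match.arg(noise_spectrum)
  if (n_switching >= n_trials) abort("need at least one location-fixed trial")
  if (n_switching > 0 && switch_range_s[2] >= duration_s) {
    abort("switch_range_s must lie strictly inside the trial duration")
  }
  with_seed(seed, {
    trf1 <- generate_trf(fs = config$fs_proc,
                         lag_span_ms = config$lag_range_ms)
    trf2 <- generate_trf(fs = config$fs_proc,
                         lag_span_ms = config$lag_range_ms)
    model <- forward_model(trf1, trf2,
                           gain_attended = gain_attended,
                           gain_unattended = gain_unattended,
                           noise_sd = noise_sd,
                           noise_spectrum = noise_spectrum,
                           lapse_s = lapse_s)
    # balanced sides, pseudo-random order
    sides <- sample(rep(c("left", "right"), length.out = n_trials))
    # switching trials live in the test portion (after the training block)
    candidates <- seq(min(n_train + 1, n_trials), n_trials)
    sw_idx <- sort(sample(candidates, n_switching))
    rows <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      is_sw <- k %in% sw_idx
      md <- trial_metadata(
        trial_id = sprintf("trial%02d", k),
        attended_speaker = 1,
        attended_side_initial = sides[k],
        kind = if (is_sw) "switching" else "fixed",
        switch_time_s = if (is_sw) runif(1, switch_range_s[1], switch_range_s[2]) else NA_real_,
        duration_s = duration_s
      )
      env1 <- generate_envelope(duration_s, config$fs_proc, speaker_id = 1)
      env2 <- generate_envelope(duration_s, config$fs_proc, speaker_id = 2)
      eeg <- simulate_trial(env1, env2, model, md, fs_acq = config$fs_acq)
      rows[[k]] <- dplyr::mutate(md, eeg = list(eeg),
                                 env1 = list(env1), env2 = list(env2))
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "config") <- config
    attr(out, "seed") <- seed
    attr(out, "model") <- model
    class(out) <- c("aad_dataset", class(out))
    out
  })
}

#' Write / read a synthetic dataset as plain-text files
#'
#' Writes one EEG table and two envelope files per trial plus a
#' `manifest.tsv` holding the ground-truth metadata; `read_dataset()`
#' reconstructs the tibble from such a directory.
#'
#' @param dataset An `aad_dataset`.
#' @param dir Directory (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns an `aad_dataset`-shaped tibble.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- dplyr::select(tibble::as_tibble(dataset),
                            !dplyr::any_of(c("eeg", "env1", "env2")))
  write_results(manifest, file.path(dir, "manifest.tsv"))
  for (k in seq_len(nrow(dataset))) {
    id <- dataset$trial_id[k]
    write_eeg(dataset$eeg[[k]], file.path(dir, paste0(id, "_eeg.tsv")))
    write_envelope(dataset$env1[[k]], file.path(dir, paste0(id, "_env1.tsv")))
    write_envelope(dataset$env2[[k]], file.path(dir, paste0(id, "_env2.tsv")))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) abort(sprintf("no manifest.tsv under %s", dir))
  manifest <- read_results(mpath)
  out <- manifest |>
    dplyr::mutate(
      eeg = purrr::map(.data$trial_id,
                       ~ read_eeg(file.path(dir, paste0(.x, "_eeg.tsv")))),
      env1 = purrr::map(.data$trial_id,
                        ~ read_envelope(file.path(dir, paste0(.x, "_env1.tsv")))),
      env2 = purrr::map(.data$trial_id,
                        ~ read_envelope(file.path(dir, paste0(.x, "_env2.tsv"))))
    )
  class(out) <- c("aad_dataset", class(out))
  out
}
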