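# Preprocessing chain shared by the offline and simulated real-time paths:
# common-average reference -> zero-phase band-pass -> polyphase resampling
# -> per-channel z-scoring. The same chain is applied either to a whole
# trial or, causally, to each 15-s buffer of the streaming loop.

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# FIR designs, filter coefficients and resampling operators are cached:
# the streaming loop resamples thousands of identically sized buffers with
# the same rational factor.
.fir_cache <- new.env(parent = emptyenv())
.rmat_cache <- new.env(parent = emptyenv())
.butter_cache <- new.env(parent = emptyenv())

fir_for <- function(p, q) {
  key <- paste(p, q, sep = "/")
  h <- .fir_cache[[key]]
  if (is.null(h)) {
    ord <- 2L * 10L * max(p, q)                 # even order -> integer delay
    h <- signal::fir1(ord, 1 / max(p, q))
    # normalize every polyphase branch to unit DC gain so constants are
    # preserved exactly regardless of the output phase
    for (r in seq_len(p) - 1L) {
      idx <- which((seq_along(h) - 1L) %% p == r)
      s <- sum(h[idx]) * p
      if (abs(s - 1) < 0.2) h[idx] <- h[idx] / s
    }
    .fir_cache[[key]] <- h
  }
  h
}

butter_for <- function(fs, low, high) {
  key <- paste(fs, low, high, sep = "/")
  b <- .butter_cache[[key]]
  if (is.null(b)) {
    b <- signal::butter(3, c(low, high) / (fs / 2), "pass")
    .butter_cache[[key]] <- b
  }
  b
}

# Linear convolution via FFT with a composite-friendly padded length
# (stats::convolve pads to n + m - 1, which can hit large prime factors
# and degrade the FFT badly).
fft_conv <- function(a, b) {
  n <- length(a) + length(b) - 1
  len <- stats::nextn(n, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(a, numeric(len - length(a)))) *
                       stats::fft(c(b, numeric(len - length(b)))),
                     inverse = TRUE)) / len
  y[seq_len(n)]
}

# Sparse banded operator equivalent of resample_rational():
# out = H %*% x with H[m, j] = p * h[(m-1) q - (j-1) p + d + 1]. Each
# output sample touches only ~length(h)/p inputs, so H is a narrow band;
# cached per (p, q, n).
resample_matrix <- function(p, q, n, target_len) {
  key <- paste(p, q, n, sep = "/")
  H <- .rmat_cache[[key]]
  if (!is.null(H)) return(H)
  h <- fir_for(p, q)
  d <- (length(h) - 1) / 2
  kw <- floor((length(h) - 1) / p) + 2L
  m <- rep(seq_len(target_len), each = kw)
  j_start <- ceiling(((m - 1) * q + d + 1 - length(h)) / p) + 1
  j <- j_start + rep(seq_len(kw) - 1L, times = target_len)
  idx <- (m - 1) * q - (j - 1) * p + d + 1
  ok <- idx >= 1 & idx <= length(h) & j >= 1 & j <= n
  H <- Matrix::sparseMatrix(i = m[ok], j = j[ok], x = h[idx[ok]] * p,
                            dims = c(target_len, n))
  .rmat_cache[[key]] <- H
  H
}

# Delay-compensated rational resampler (upsample by p, windowed-sinc
# low-pass, downsample by q). Unlike a plain polyphase call, the FIR group
# delay is removed so resampled signals stay time-aligned with the input,
# and the signal is edge-replicated before filtering so boundaries do not
# droop toward zero. `x` may be a vector or a matrix whose rows are
# channels.
resample_rational <- function(x, p, q) {
  g <- gcd2(p, q)
  p <- p / g; q <- q / g
  if (p == 1 && q == 1) return(x)
  is_mat <- is.matrix(x)
  n0 <- if (is_mat) ncol(x) else length(x)
  target0 <- round(n0 * p / q)
  # pad with q edge-replicated input samples so exactly p output samples
  # can be dropped on each side afterwards
  npad <- ceiling((20 * max(p, q)) / (2 * p) / q) * q
  drop_out <- npad * p / q
  if (is_mat) {
    x <- cbind(x[, rep(1L, npad), drop = FALSE], x,
               x[, rep(n0, npad), drop = FALSE])
  } else {
    x <- c(rep(x[1], npad), x, rep(x[n0], npad))
  }
  n <- n0 + 2 * npad
  target_len <- round(n * p / q)
  h <- fir_for(p, q)
  band_nnz <- as.numeric(target_len) * (length(h) / p + 2)
  if (band_nnz <= 5e6) {
    H <- resample_matrix(p, q, n, target_len)
    out <- if (is_mat) as.matrix(Matrix::tcrossprod(x, H)) else
      as.numeric(H %*% x)
  } else if (is_mat) {
    inner <- x[, (npad + 1):(npad + n0), drop = FALSE]
    return(t(apply(inner, 1, resample_rational, p = p, q = q)))
  } else {
    up <- numeric(n * p)
    up[seq(1, n * p, by = p)] <- x * p
    d <- (length(h) - 1) / 2
    y <- fft_conv(up, h)
    y <- y[(d + 1):(d + n * p)]
    out <- y[seq(1, n * p, by = q)]
  }
  if (is_mat) {
    out[, (drop_out + 1):(drop_out + target0), drop = FALSE]
  } else {
    out[(drop_out + 1):(drop_out + target0)]
  }
}

#' Zero-phase band-pass filter
#'
#' Order-3 Butterworth applied forward and backward (`signal::filtfilt`),
#' so the pass band keeps zero phase. At sampling rates far above the band
#' (normalized upper edge below 0.01, e.g. audio rates with an 8 Hz edge)
#' the IIR design is numerically unusable, so the filter runs at an
#' internally decimated rate (anti-aliased, delay-compensated) and the
#' result is interpolated back to `fs` — still zero phase end to end.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs, low, high) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("band edges must satisfy 0 < low < high < fs/2")
  }
  if (high / (fs / 2) < 0.01) {
    k <- floor(fs / (16 * high))
    dn <- decimate_staged(x, k)
    fl <- signal::filtfilt(butter_for(fs / k, low, high), dn)
    up <- resample_rational(fl, k, 1)
    n <- length(x)
    if (length(up) >= n) return(up[seq_len(n)])
    return(c(up, rep(up[length(up)], n - length(up))))
  }
  signal::filtfilt(butter_for(fs, low, high), x)
}

#' Anti-aliased downsampling
#'
#' Rational-factor polyphase resampling (`fs_to`/`fs_from` reduced to lowest
#' terms), delay-compensated so the output stays aligned with the input.
#' The pipeline only ever reduces the rate (125 to 64 Hz); an upsampling
#' request is rejected.
#'
#' @param x Numeric vector.
#' @param fs_from,fs_to Rates in Hz with `fs_from > fs_to`.
#' @return Vector of length `round(length(x) * fs_to / fs_from)` (within
#'   one sample).
#' @export
resample_signal <- function(x, fs_from, fs_to) {
  if (fs_to >= fs_from) abort("resample_signal() only downsamples (fs_to < fs_from)")
  r <- ratio_int(fs_to, fs_from)
  p <- r[1]; q <- r[2]
  # extreme ratios (audio rates -> 64 Hz) run as staged integer decimations
  # so intermediate signals stay small; each stage is anti-aliased and
  # delay-compensated.
  while (q > 16 * p) {
    f <- largest_small_divisor(q, 10)
    if (f == 1) break
    x <- resample_rational(x, 1, f)
    q <- q / f
  }
  resample_rational(x, p, q)
}

decimate_staged <- function(x, k) {
  while (k > 1) {
    f <- largest_small_divisor(k, 10)
    if (f == 1) f <- k                 # prime factor beyond 10: single stage
    x <- resample_rational(x, 1, f)
    k <- k / f
  }
  x
}

largest_small_divisor <- function(q, limit) {
  for (f in seq(min(limit, q), 2)) if (q %% f == 0) return(f)
  1
}

# small rational approximation of fs_to/fs_from for integer-ish rates
ratio_int <- function(a, b) {
  s <- 1
  while (abs(a * s - round(a * s)) > 1e-9 || abs(b * s - round(b * s)) > 1e-9) {
    s <- s * 10
    if (s > 1e6) abort("sampling rates must be rational with small denominators")
  }
  p <- round(a * s); q <- round(b * s)
  g <- gcd2(p, q)
  c(p / g, q / g)
}

#' z-score a signal
#'
#' Centers and scales to mean 0 and unit *population* standard deviation
#' (divide by N, not N-1); the convention is fixed so snippet-level and
#' trial-level standardization are reproducible.
#'
#' @param x Numeric vector.
#' @return Standardized vector.
#' @export
zscore <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s <= 1e-12) {
    abort("degenerate signal: zero variance, z-score undefined")
  }
  (x - m) / s
}

#' Re-reference EEG to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' at each sample the channel mean is zero. Requires at least two channels
#' and a trial still at its recording reference.
#'
#' @param trial An [eeg_trial()].
#' @return The re-referenced [eeg_trial()] with `reference = "common-average"`.
#' @export
rereference_common_average <- function(trial) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (trial$reference != "recording-reference") {
    abort("trial is already re-referenced")
  }
  if (nrow(trial$data) < 2) {
    abort("common-average reference needs at least 2 channels")
  }
  trial$data <- sweep(trial$data, 2, colMeans(trial$data), "-")
  trial$reference <- "common-average"
  trial
}

#' Extract a speech envelope from audio
#'
#' Fixed five-step pipeline: analytic signal (Hilbert transform via FFT),
#' magnitude, band-pass at the configured pass band, resampling to the
#' processing rate, z-scoring. The result is the standardized slow amplitude
#' envelope the backward decoder is trained against.
#'
#' @param waveform Numeric vector, audio samples.
#' @param fs_audio Audio sampling rate in Hz (must exceed twice the upper
#'   band edge).
#' @param config An [aad_config()].
#' @param speaker_id Identifier stored with the envelope.
#' @return An [envelope()] at `config$fs_proc` with `standardized = TRUE`.
#' @export
extract_envelope <- function(waveform, fs_audio, config = aad_config(),
                             speaker_id = NA) {
  if (length(waveform) < fs_audio) abort("need at least 1 s of audio")
  if (fs_audio <= 2 * config$passband_hz[2]) {
    abort("audio rate must exceed twice the passband upper edge")
  }
  mag <- Mod(analytic_signal(waveform))
  bp <- bandpass(mag, fs_audio, config$passband_hz[1], config$passband_hz[2])
  ds <- resample_signal(bp, fs_audio, config$fs_proc)
  envelope(zscore(ds), fs = config$fs_proc, standardized = TRUE,
           speaker_id = speaker_id)
}

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Preprocess a whole EEG trial
#'
#' Applies, in this order: common-average re-referencing, zero-phase
#' band-pass at the configured pass band, downsampling to the processing
#' rate, and per-channel z-scoring. The order matters and is fixed.
#'
#' @param trial A raw [eeg_trial()] at `config$fs_acq`.
#' @param config An [aad_config()].
#' @return An [eeg_trial()] at `config$fs_proc`, each channel mean 0 / SD 1.
#' @export
preprocess_eeg <- function(trial, config = aad_config()) {
  stopifnot(inherits(trial, "eeg_trial"))
  trial <- rereference_common_average(trial)
  proc <- preprocess_matrix(trial$data, trial$fs, config)
  eeg_trial(proc, fs = config$fs_proc, channel_labels = trial$channel_labels,
            reference = "common-average", trial_id = trial$trial_id)
}

# band-pass + resample + z-score each row of a (already re-referenced)
# matrix; the resampling step runs on all channels at once.
preprocess_matrix <- function(data, fs_from, config) {
  bp <- t(apply(data, 1, bandpass, fs = fs_from,
                low = config$passband_hz[1], high = config$passband_hz[2]))
  if (fs_from != config$fs_proc) {
    bp <- resample_signal(bp, fs_from, config$fs_proc)
  }
  t(apply(bp, 1, zscore))
}

#' Preprocess one streaming buffer into a snippet
#'
#' Applies the whole-trial chain of [preprocess_eeg()] to a single W-second
#' buffer, using no samples outside the buffer (causally realizable in a
#' streaming loop), and cuts the matching W-second segments from the stored
#' full-trial speech envelopes, re-z-scoring each segment.
#'
#' @param buffer Channels x samples matrix (or [eeg_trial()]) at
#'   `config$fs_acq`, spanning exactly `config$window_s` seconds, at the
#'   recording reference.
#' @param envelopes List of standardized full-trial [envelope()]s at
#'   `config$fs_proc` (one per speaker).
#' @param config An [aad_config()].
#' @param i Window index (1-based); window i ends at
#'   `buffer_s + (i - 1) * step_s` seconds.
#' @return An `aad_snippet`: list with `eeg` (channels x `W * fs_proc`
#'   matrix), `segments` (list of numeric vectors), `window`, `window_end_s`.
#' @export
preprocess_snippet <- function(buffer, envelopes, config = aad_config(), i = 1L) {
  if (inherits(buffer, "eeg_trial")) buffer <- buffer$data
  need <- round(config$window_s * config$fs_acq)
  if (ncol(buffer) < need) {
    abort(sprintf("buffer underrun: %d samples given, %d needed for a %g-s window",
                  ncol(buffer), need, config$window_s))
  }
  if (ncol(buffer) > need) buffer <- buffer[, seq_len(need), drop = FALSE]
  buffer <- sweep(buffer, 2, colMeans(buffer), "-")   # common average
  eeg <- preprocess_matrix(buffer, config$fs_acq, config)
  end_s <- config$buffer_s + (i - 1) * config$step_s
  n_win <- round(config$window_s * config$fs_proc)
  segments <- lapply(envelopes, function(env) {
    stopifnot(inherits(env, "envelope"))
    idx_end <- round(end_s * env$fs)
    idx <- (idx_end - n_win + 1):idx_end
    if (idx[1] < 1 || idx_end > length(env$values)) {
      abort("window extends beyond the stored envelope")
    }
    zscore(env$values[idx])
  })
  structure(list(eeg = eeg, segments = segments,
                 window = as.integer(i), window_end_s = end_s),
            class = "aad_snippet")
}
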