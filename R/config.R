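#' Experiment configuration
#'
#' Bundles every tunable parameter of the decoding pipeline. Defaults follow
#' the portable two-speaker AAD protocol: EEG acquired at 125 Hz, analysed at
#' 64 Hz in the 0.5--8 Hz band, ridge penalty \eqn{\lambda = 10} with decoder
#' lags spanning 0--250 ms post-stimulus, a 15-s sliding window advanced every
#' 1 s, and exponential-moving-average smoothing with \eqn{\alpha = 0.1}.
#'
#' @param passband_hz Length-2 numeric, band-pass edges in Hz.
#' @param fs_acq Acquisition sampling rate in Hz.
#' @param fs_proc Processing (analysis) sampling rate in Hz.
#' @param lambda_reg Ridge regularization parameter \eqn{\lambda}, applied
#'   un-normalized to the diagonal of the lagged covariance.
#' @param lag_range_ms Length-2 numeric, decoder time-lag range in ms
#'   (EEG lags the stimulus).
#' @param window_s Sliding-window width W in seconds.
#' @param step_s Window step M in seconds.
#' @param buffer_s Initial buffer accumulation in seconds (equals `window_s`
#'   in the reference protocol).
#' @param ema_alpha EMA weight \eqn{\alpha \in (0, 1]} for correlation
#'   smoothing.
#' @param seed Integer seed recorded with the configuration.
#'
#' @return An object of class `aad_config` (a named list).
#' @export
#' @examples
#' cfg <- aad_config()
#' cfg$lambda_reg
#' n_decoder_lags(cfg)
aad_config <- function(passband_hz = c(0.5, 8),
                       fs_acq = 125,
                       fs_proc = 64,
                       lambda_reg = 10,
                       lag_range_ms = c(0, 250),
                       window_s = 15,
                       step_s = 1,
                       buffer_s = window_s,
                       ema_alpha = 0.1,
                       seed = 1L) {
  cfg <- list(
    passband_hz = as.numeric(passband_hz),
    fs_acq = as.numeric(fs_acq),
    fs_proc = as.numeric(fs_proc),
    lambda_reg = as.numeric(lambda_reg),
    lag_range_ms = as.numeric(lag_range_ms),
    window_s = as.numeric(window_s),
    step_s = as.numeric(step_s),
    buffer_s = as.numeric(buffer_s),
    ema_alpha = as.numeric(ema_alpha),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "aad_config")
}

validate_config <- function(cfg) {
  if (length(cfg$passband_hz) != 2 || cfg$passband_hz[1] >= cfg$passband_hz[2]) {
    abort("`passband_hz` must be (low, high) with low < high")
  }
  if (cfg$passband_hz[1] <= 0) abort("passband low edge must be > 0")
  if (cfg$fs_acq <= 0 || cfg$fs_proc <= 0) abort("sampling rates must be positive")
  if (cfg$passband_hz[2] >= cfg$fs_proc / 2) {
    abort("passband high edge must be below the processing Nyquist rate")
  }
  if (length(cfg$lag_range_ms) != 2 || any(cfg$lag_range_ms < 0) ||
      cfg$lag_range_ms[1] > cfg$lag_range_ms[2]) {
    abort("`lag_range_ms` must be a non-negative, non-decreasing pair")
  }
  if (cfg$step_s <= 0 || cfg$window_s < cfg$step_s) {
    abort("need window_s >= step_s > 0")
  }
  if (cfg$buffer_s < cfg$window_s) abort("buffer_s must be at least window_s")
  if (cfg$ema_alpha <= 0 || cfg$ema_alpha > 1) {
    abort("`ema_alpha` must lie in (0, 1]")
  }
  invisible(cfg)
}

#' @export
print.aad_config <- function(x, ...) {
  cat("<aad_config>\n")
  cat(sprintf("  passband   : %.3g-%.3g Hz\n", x$passband_hz[1], x$passband_hz[2]))
  cat(sprintf("  rates      : %g Hz acquisition -> %g Hz processing\n",
              x$fs_acq, x$fs_proc))
  cat(sprintf("  ridge      : lambda = %g, lags %g-%g ms (%d taps)\n",
              x$lambda_reg, x$lag_range_ms[1], x$lag_range_ms[2],
              n_decoder_lags(x)))
  cat(sprintf("  window     : W = %g s, step M = %g s, buffer %g s\n",
              x$window_s, x$step_s, x$buffer_s))
  cat(sprintf("  EMA alpha  : %g\n", x$ema_alpha))
  invisible(x)
}

#' Decoder lag indices for a configuration
#'
#' Converts the configured lag range in milliseconds to integer sample lags
#' at the processing rate. The 0--250 ms default at 64 Hz yields lags
#' 0, 1, ..., 16 (17 taps).
#'
#' @param config An [aad_config()].
#' @return Integer vector of sample lags (0-based).
#' @export
decoder_lags <- function(config) {
  lo <- floor(config$lag_range_ms[1] / 1000 * config$fs_proc)
  hi <- floor(config$lag_range_ms[2] / 1000 * config$fs_proc)
  seq.int(lo, hi)
}

#' @rdname decoder_lags
#' @export
n_decoder_lags <- function(config) length(decoder_lags(config))

#' Read / write a configuration file
#'
#' Flat `key = value` text files mirroring the [aad_config()] fields;
#' length-2 fields are comma-separated. Unknown keys are an error so typos
#' do not silently fall back to defaults.
#'
#' @param path File path.
#' @param config An [aad_config()].
#' @return `read_config()` returns an [aad_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- aad_config()
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) abort(sprintf("unknown config key: '%s'", key))
    vals[[key]] <- as.numeric(strsplit(trimws(kv[2]), ",")[[1]])
  }
  do.call(aad_config, modifyList(unclass(defaults), vals))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "aad_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(format(config[[k]], digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
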