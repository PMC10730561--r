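#' Read and write EEG trials
#'
#' Two on-disk representations are supported: a plain tab-separated table
#' (one row per channel, `#`-prefixed sidecar header lines carrying the
#' sampling rate, channel labels, reference state and trial id) and 16-bit
#' EDF. The table dialect round-trips values to better than 1e-12; EDF is
#' limited by its 16-bit quantization and 8-character physical-range fields.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.edf` vs anything else),
#'   `"table"`, or `"edf"`.
#' @param trial An [eeg_trial()].
#' @return `read_eeg()` returns an [eeg_trial()] with
#'   `reference = "recording-reference"` unless the file says otherwise;
#'   `write_eeg()` returns `path` invisibly.
#' @export
read_eeg <- function(path, format = c("auto", "table", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "table"
  }
  if (!file.exists(path)) abort(sprintf("EEG file not found: %s", path))
  switch(format, table = read_eeg_table(path), edf = read_eeg_edf(path))
}

#' @rdname read_eeg
#' @export
write_eeg <- function(trial, path, format = c("auto", "table", "edf")) {
  stopifnot(inherits(trial, "eeg_trial"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "table"
  }
  switch(format,
    table = write_eeg_table(trial, path),
    edf = write_eeg_edf(trial, path))
  invisible(path)
}

parse_header_lines <- function(lines) {
  hdr <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in hdr) {
    body <- sub("^#\\s*", "", ln)
    parts <- strsplit(body, "\t")[[1]]
    if (length(parts) < 2) abort(sprintf("garbled header line: '%s'", ln))
    out[[parts[1]]] <- parts[-1]
  }
  out
}

read_eeg_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_header_lines(lines)
  if (is.null(hdr$fs)) abort("EEG table header is missing '# fs'")
  if (is.null(hdr$channels)) abort("EEG table header is missing '# channels'")
  fs <- as.numeric(hdr$fs[1])
  if (is.na(fs)) abort("EEG table header has a non-numeric fs")
  labels <- hdr$channels
  reference <- if (!is.null(hdr$reference)) hdr$reference[1] else "recording-reference"
  trial_id <- if (!is.null(hdr$trial_id)) hdr$trial_id[1] else "trial"
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) != length(labels)) {
    abort(sprintf("EEG table has %d data rows but %d channel labels",
                  length(body), length(labels)))
  }
  rows <- lapply(body, function(ln) {
    suppressWarnings(as.numeric(strsplit(ln, "\t")[[1]]))
  })
  ns <- unique(lengths(rows))
  if (length(ns) != 1) abort("EEG table rows have unequal sample counts")
  data <- do.call(rbind, rows)
  nan_rows <- which(vapply(rows, anyNA, logical(1)))
  if (length(nan_rows)) {
    abort(sprintf("non-numeric/NaN samples in channel(s): %s",
                  paste(labels[nan_rows], collapse = ", ")))
  }
  eeg_trial(data, fs = fs, channel_labels = labels,
            reference = reference, trial_id = trial_id)
}

write_eeg_table <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# fs\t", format(trial$fs, digits = 17)),
    paste0("# reference\t", trial$reference),
    paste0("# trial_id\t", trial$trial_id),
    paste0("# channels\t", paste(trial$channel_labels, collapse = "\t"))
  ), con)
  for (i in seq_len(nrow(trial$data))) {
    writeLines(paste(sprintf("%.17g", trial$data[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

# ---- EDF (16-bit, 1-s data records) -----------------------------------------
# Minimal European Data Format codec: ASCII fixed-width headers followed by
# little-endian int16 samples, one 1-s record per block. Enough for storing
# and re-reading trials; no annotations, no EDF+.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

write_eeg_edf <- function(trial, path) {
  fs <- trial$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- ncol(trial$data)
  if (n %% fs != 0) abort("EDF export needs a whole number of 1-s records")
  n_rec <- n %/% fs
  ns <- nrow(trial$data)
  phys_max <- apply(abs(trial$data), 1, max)
  phys_max[phys_max == 0] <- 1
  # physical range is serialized in 8 ASCII chars; keep it representable
  phys_max <- as.numeric(sprintf("%.6g", phys_max * 1.000001))
  dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("aadkit subject", 80), edf_pad("aadkit recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(trial$channel_labels, edf_pad, "", width = 16), collapse = ""),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad("uV", 8), ns),
    paste(vapply(-phys_max, function(v) edf_pad(sprintf("%.6g", v), 8), ""), collapse = ""),
    paste(vapply(phys_max, function(v) edf_pad(sprintf("%.6g", v), 8), ""), collapse = ""),
    strrep(edf_pad(-dig_max, 8), ns),
    strrep(edf_pad(dig_max, 8), ns),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad(fs, 8), ns),
    strrep(edf_pad("", 32), ns)
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  digital <- round(sweep(trial$data, 1, phys_max, "/") * dig_max)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- as.integer(t(digital[, cols, drop = FALSE]))
    writeBin(block, con, size = 2, endian = "little")
  }
  invisible(path)
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (nchar(out, type = "bytes") < w) abort("truncated EDF header")
    trimws(out)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(rec_dur) || is.na(ns) || ns < 1) {
    abort("garbled EDF header")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)          # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) abort("EDF signals with mixed rates are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1], size = 2,
                     endian = "little", signed = TRUE)
    if (length(block) < ns * spr[1]) abort("truncated EDF data record")
    blk <- matrix(block, nrow = spr[1], ncol = ns)
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(blk)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- sweep(sweep(data, 1, dig_min, "-"), 1, scale, "*") + phys_min
  eeg_trial(data, fs = fs, channel_labels = labels,
            reference = "recording-reference",
            trial_id = sub("\\.edf$", "", basename(path), ignore.case = TRUE))
}

# ---- WAV --------------------------------------------------------------------

#' Read a WAV audio file
#'
#' Minimal RIFF/WAVE reader for 16/24-bit PCM and 32-bit float files,
#' mono or stereo. Samples are returned as floating point in \[-1, 1\].
#' For stereo files column 1 is the left channel, i.e. the speaker
#' presented at the left ear in the dichotic paradigm.
#'
#' @param path WAV file path.
#' @return A list with `data` (samples x channels matrix) and `fs` (Hz).
#' @export
read_audio <- function(path) {
  if (!file.exists(path)) abort(sprintf("audio file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file")
  readBin(con, integer(), 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a RIFF/WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id, type = "bytes") < 4) break
    size <- readBin(con, integer(), 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, raw(), size)
      if (length(raw) < 16) abort("truncated fmt chunk")
      u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2), fs = u32(4), bits = u16(14))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), size)
      if (length(data_raw) < size) abort("truncated WAV data chunk")
    } else {
      seek(con, size + size %% 2, origin = "current")
      next
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("WAV file is missing fmt/data chunks")
  nch <- fmt$channels
  x <- switch(as.character(fmt$bits),
    "16" = {
      if (fmt$format != 1) abort("unsupported WAV encoding")
      v <- readBin(data_raw, integer(), length(data_raw) %/% 2, size = 2,
                   endian = "little", signed = TRUE)
      v / 32767
    },
    "24" = {
      if (fmt$format != 1) abort("unsupported WAV encoding")
      n <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$format != 3) abort("unsupported WAV encoding")
      readBin(data_raw, numeric(), length(data_raw) %/% 4, size = 4,
              endian = "little")
    },
    abort(sprintf("unsupported WAV bit depth: %d", fmt$bits))
  )
  n_frames <- length(x) %/% nch
  data <- matrix(x[seq_len(n_frames * nch)], ncol = nch, byrow = TRUE)
  list(data = data, fs = fmt$fs)
}

#' Write a WAV audio file
#'
#' Counterpart of [read_audio()]; writes 16-bit PCM. Mainly used to create
#' self-contained examples and round-trip tests.
#'
#' @param data Numeric vector (mono) or samples x channels matrix in
#'   \[-1, 1\]; values are clipped.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audio <- function(data, fs, path) {
  data <- as.matrix(data)
  nch <- ncol(data)
  v <- as.vector(t(data))
  v <- pmin(pmax(v, -1), 1)
  pcm <- as.integer(round(v * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * 2), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# ---- envelopes, results, decoders ------------------------------------------

#' Read / write a speech envelope
#'
#' Single-column TSV with `#`-prefixed header lines (`fs`, `speaker_id`,
#' `standardized`). Round-trips to better than 1e-12.
#'
#' @param env An [envelope()].
#' @param path File path.
#' @return `read_envelope()` returns an [envelope()]; `write_envelope()`
#'   returns `path` invisibly.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "envelope"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# fs\t", format(env$fs, digits = 17)),
    paste0("# speaker_id\t", as.character(env$speaker_id)),
    paste0("# standardized\t", if (env$standardized) "true" else "false")
  ), con)
  writeLines(sprintf("%.17g", env$values), con)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  if (!file.exists(path)) abort(sprintf("envelope file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_header_lines(lines)
  if (is.null(hdr$fs)) abort("envelope file is missing '# fs'")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  envelope(as.numeric(body), fs = as.numeric(hdr$fs[1]),
           standardized = identical(hdr$standardized[1], "true"),
           speaker_id = hdr$speaker_id[1] %||% NA)
}

#' Write / read tabular results
#'
#' Tab-separated tables with a header row; numeric columns are serialized at
#' full double precision so a read-back reproduces values to better than
#' 1e-12. The real-time trace schema is `trial_id`, `window`,
#' `window_end_s`, `r1_raw`, `r2_raw`, `r1_ema`, `r2_ema`, `decision`,
#' `correct` (see [stream_decode()]); any other data frame is written with
#' its own columns.
#'
#' @param records A non-empty data frame.
#' @param path File path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a tibble.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) abort("refusing to write an empty results table")
  fmt <- lapply(records, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(paste(names(records), collapse = "\t"),
             do.call(paste, c(fmt, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("results file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Serialize a fitted decoder
#'
#' TSV matrix (rows = lags, columns = channels) with `#`-header lines for
#' the ridge parameter, lag list, processing rate and channel labels.
#'
#' @param decoder An [aad_decoder] as returned by [fit_ridge_decoder()].
#' @param path File path.
#' @return `read_decoder()` returns an `aad_decoder`; `write_decoder()`
#'   returns `path` invisibly.
#' @export
write_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "aad_decoder"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# lambda\t", format(decoder$lambda, digits = 17)),
    paste0("# fs_proc\t", format(decoder$fs, digits = 17)),
    paste0("# lags\t", paste(decoder$lag_samples, collapse = "\t")),
    paste0("# channels\t", paste(decoder$channel_labels, collapse = "\t"))
  ), con)
  for (i in seq_len(nrow(decoder$weights))) {
    writeLines(paste(sprintf("%.17g", decoder$weights[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  if (!file.exists(path)) abort(sprintf("decoder file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_header_lines(lines)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  w <- do.call(rbind, lapply(body, function(ln) as.numeric(strsplit(ln, "\t")[[1]])))
  fs <- if (identical(hdr$fs_proc[1], "NA")) NA_real_ else as.numeric(hdr$fs_proc[1])
  new_decoder(w, lambda = as.numeric(hdr$lambda[1]),
              lag_samples = as.integer(hdr$lags),
              fs = fs, channel_labels = hdr$channels)
}
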