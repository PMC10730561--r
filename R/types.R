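#' EEG trial container
#'
#' A channels-by-samples matrix with its sampling rate, ordered channel
#' labels, referencing state and an identifier. Channel order is never
#' silently changed by any operation in the package.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param reference `"recording-reference"` (as acquired) or
#'   `"common-average"` (after [rereference_common_average()]).
#' @param trial_id Identifier string.
#'
#' @return An object of class `eeg_trial`.
#' @export
#' @examples
#' tr <- eeg_trial(matrix(rnorm(30), 3), fs = 10,
#'                 channel_labels = c("Fz", "Cz", "Pz"))
#' duration_s(tr)
eeg_trial <- function(data, fs, channel_labels,
                      reference = c("recording-reference", "common-average"),
                      trial_id = "trial") {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != length(channel_labels)) {
    abort(sprintf("data has %d rows but %d channel labels were given",
                  nrow(data), length(channel_labels)))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("fs must be a positive scalar")
  bad <- which(!apply(data, 1, function(r) all(is.finite(r))))
  if (length(bad)) {
    abort(sprintf("non-finite values in channel(s): %s",
                  paste(channel_labels[bad], collapse = ", ")))
  }
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         reference = reference, trial_id = as.character(trial_id)),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial '%s'> %d channels x %d samples @ %g Hz (%.6g s), %s\n",
              x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              duration_s(x), x$reference))
  invisible(x)
}

#' Duration of a trial or envelope in seconds
#' @param x An `eeg_trial` or `envelope`.
#' @return Numeric scalar, seconds.
#' @export
duration_s <- function(x) UseMethod("duration_s")

#' @export
duration_s.eeg_trial <- function(x) ncol(x$data) / x$fs

#' @export
duration_s.envelope <- function(x) length(x$values) / x$fs

#' @describeIn eeg_trial long-format view: one row per (channel, sample)
#'   with columns `channel`, `time_s`, `value`.
#' @param x An `eeg_trial`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eeg_trial <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_labels, times = ncol(x$data)),
    time_s = rep((seq_len(ncol(x$data)) - 1) / x$fs, each = nrow(x$data)),
    value = as.vector(x$data)
  )
}

#' Speech-envelope container
#'
#' A single-rate amplitude-envelope vector with its sampling rate, a flag
#' recording whether it has been z-scored, and the speaker it belongs to.
#'
#' @param values Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param standardized Logical; `TRUE` once the vector has been z-scored
#'   (mean 0, population SD 1).
#' @param speaker_id Identifier (typically 1 or 2).
#'
#' @return An object of class `envelope`.
#' @export
envelope <- function(values, fs, standardized = FALSE, speaker_id = NA) {
  values <- as.numeric(values)
  if (!is.numeric(fs) || fs <= 0) abort("fs must be a positive scalar")
  if (anyNA(values) || any(!is.finite(values))) abort("envelope contains non-finite values")
  if (isTRUE(standardized)) {
    m <- mean(values)
    s <- sqrt(mean((values - m)^2))
    if (abs(m) > 1e-6 || abs(s - 1) > 1e-6) {
      abort("standardized = TRUE but values are not z-scored (mean 0, sd 1)")
    }
  }
  structure(list(values = values, fs = as.numeric(fs),
                 standardized = isTRUE(standardized), speaker_id = speaker_id),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope speaker %s> %d samples @ %g Hz (%.6g s)%s\n",
              as.character(x$speaker_id), length(x$values), x$fs, duration_s(x),
              if (x$standardized) ", z-scored" else ""))
  invisible(x)
}

#' Per-trial metadata row
#'
#' One row of experiment bookkeeping: which speaker was attended, which ear
#' it was presented to at trial start, whether (and when) the presentation
#' side switched, and the trial duration. Switching trials keep the attended
#' *speaker* constant; only the ear of presentation changes.
#'
#' @param trial_id Identifier.
#' @param attended_speaker 1 or 2.
#' @param attended_side_initial `"left"` or `"right"`.
#' @param kind `"fixed"` or `"switching"`.
#' @param switch_time_s Switch time in seconds; must be given iff
#'   `kind == "switching"` and lie strictly inside the trial.
#' @param duration_s Trial duration in seconds.
#'
#' @return A one-row tibble.
#' @export
#' @examples
#' trial_metadata("t01", 1, "left", "switching", switch_time_s = 29, duration_s = 60)
trial_metadata <- function(trial_id, attended_speaker,
                           attended_side_initial = c("left", "right"),
                           kind = c("fixed", "switching"),
                           switch_time_s = NA_real_, duration_s = 60) {
  kind <- match.arg(kind)
  attended_side_initial <- match.arg(attended_side_initial)
  if (!attended_speaker %in% c(1, 2)) abort("attended_speaker must be 1 or 2")
  if (kind == "switching") {
    if (is.na(switch_time_s)) abort("switching trials need a switch_time_s")
    if (switch_time_s <= 0 || switch_time_s >= duration_s) {
      abort("switch_time_s must lie strictly inside the trial")
    }
  } else if (!is.na(switch_time_s)) {
    abort("fixed trials must not carry a switch_time_s")
  }
  tibble::tibble(
    trial_id = as.character(trial_id),
    attended_speaker = as.integer(attended_speaker),
    attended_side_initial = attended_side_initial,
    kind = kind,
    switch_time_s = as.numeric(switch_time_s),
    duration_s = as.numeric(duration_s)
  )
}
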