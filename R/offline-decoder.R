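# Backward (stimulus-reconstruction) model. The decoder D(tau, n) maps
# time-lagged multichannel EEG to the attended speech envelope:
#
#   S_hat(t) = sum_n sum_tau D(tau, n) R(t + tau, n)
#
# with lags tau covering 0-250 ms: the EEG *follows* the stimulus, so
# reconstructing S(t) uses EEG samples at t .. t + 250 ms. D is the ridge
# solution (X X' + lambda I)^{-1} X S' on the lag-expanded design X.

new_decoder <- function(weights, lambda, lag_samples, fs, channel_labels,
                        provenance = 1L) {
  structure(
    list(weights = weights, lambda = lambda,
         lag_samples = as.integer(lag_samples), fs = fs,
         channel_labels = channel_labels,
         provenance = as.integer(provenance)),
    class = "aad_decoder"
  )
}

#' @export
print.aad_decoder <- function(x, ...) {
  cat(sprintf(
    "<aad_decoder> %d lags x %d channels, lambda = %g, fs = %g Hz%s\n",
    nrow(x$weights), ncol(x$weights), x$lambda, x$fs,
    if (x$provenance > 1) sprintf(" (mean of %d decoders)", x$provenance) else ""))
  invisible(x)
}

#' Time-lag expansion of an EEG trial
#'
#' Builds the (lags x channels) by samples design matrix of the backward
#' model: the row for (lag tau, channel n), at output time t, holds the EEG
#' sample of channel n at time t + tau. Positions past the end of the trial
#' are zero-filled so the design keeps the full trial length. Rows are
#' ordered lag-fastest within channel.
#'
#' @param x An [eeg_trial()] at the processing rate, or a channels x samples
#'   matrix.
#' @param lag_samples Integer vector of non-negative sample lags
#'   (see [decoder_lags()]).
#' @return A matrix with `length(lag_samples) * n_channels` rows and one
#'   column per input sample; attributes `lag_samples` and `channel_labels`
#'   record the row mapping.
#' @export
build_lagged_design <- function(x, lag_samples) {
  labels <- NULL
  if (inherits(x, "eeg_trial")) {
    labels <- x$channel_labels
    x <- x$data
  }
  lag_samples <- as.integer(lag_samples)
  if (any(lag_samples < 0)) abort("lags must be non-negative")
  n_ch <- nrow(x)
  n_t <- ncol(x)
  if (max(lag_samples) >= n_t) abort("largest lag exceeds the trial length")
  n_lag <- length(lag_samples)
  design <- matrix(0, n_lag * n_ch, n_t)
  for (j in seq_len(n_lag)) {
    tau <- lag_samples[j]
    rows <- (seq_len(n_ch) - 1L) * n_lag + j
    design[rows, seq_len(n_t - tau)] <- x[, (tau + 1L):n_t, drop = FALSE]
  }
  attr(design, "lag_samples") <- lag_samples
  attr(design, "channel_labels") <- labels %||% paste0("ch", seq_len(n_ch))
  design
}

#' Fit a ridge backward decoder
#'
#' Solves the regularized normal equations
#' \eqn{D = (X X^\top + \lambda I)^{-1} X s^\top} where X is the lag-expanded
#' EEG design and s the attended speech envelope. \eqn{\lambda} is added to
#' the diagonal exactly as written — un-normalized — so the printed value
#' (default 10) is meaningful on z-scored data.
#'
#' @param design Matrix from [build_lagged_design()].
#' @param env An [envelope()] (or numeric vector) with one value per design
#'   column.
#' @param lambda Ridge parameter, `>= 0`.
#' @return An `aad_decoder` whose `weights` are a lags x channels matrix.
#' @export
fit_ridge_decoder <- function(design, env, lambda = 10) {
  s <- if (inherits(env, "envelope")) env$values else as.numeric(env)
  if (length(s) != ncol(design)) {
    abort(sprintf("envelope has %d samples but the design has %d columns",
                  length(s), ncol(design)))
  }
  if (lambda < 0) abort("lambda must be non-negative")
  lag_samples <- attr(design, "lag_samples")
  labels <- attr(design, "channel_labels")
  if (is.null(lag_samples)) abort("design must come from build_lagged_design()")
  n_lag <- length(lag_samples)
  n_ch <- nrow(design) / n_lag
  xxt <- tcrossprod(design)
  diag(xxt) <- diag(xxt) + lambda
  b <- design %*% s
  w <- tryCatch(
    solve(xxt, b),
    error = function(e) {
      abort(paste0("singular lagged covariance; use lambda > 0 ",
                   "to regularize (", conditionMessage(e), ")"))
    }
  )
  new_decoder(matrix(w, nrow = n_lag, ncol = n_ch), lambda = lambda,
              lag_samples = lag_samples, fs = NA_real_,
              channel_labels = labels)
}

#' Reconstruct a speech envelope from EEG
#'
#' Applies a fitted decoder to a lag-expanded design:
#' \eqn{\hat S = D^\top X}. The output is a raw (not standardized)
#' reconstruction of the attended envelope, one value per design column.
#'
#' @param decoder An `aad_decoder`.
#' @param design Matrix from [build_lagged_design()] with the same lag and
#'   channel structure the decoder was fit with.
#' @param fs Sampling rate stored on the returned envelope (optional).
#' @return An [envelope()] with `standardized = FALSE`.
#' @export
reconstruct_envelope <- function(decoder, design, fs = NULL) {
  stopifnot(inherits(decoder, "aad_decoder"))
  if (length(decoder$weights) != nrow(design)) {
    abort("decoder and design disagree on lag/channel structure")
  }
  lag_d <- attr(design, "lag_samples")
  if (!is.null(lag_d) && !identical(as.integer(lag_d), decoder$lag_samples)) {
    abort("decoder and design use different lag sets")
  }
  shat <- drop(crossprod(as.vector(decoder$weights), design))
  envelope(shat, fs = fs %||% (if (is.finite(decoder$fs)) decoder$fs else 1),
           standardized = FALSE, speaker_id = "reconstruction")
}

#' Classify attention from a pair of envelope correlations
#'
#' A trial (or window) is decoded correctly iff the correlation with the
#' attended speaker's envelope strictly exceeds the correlation with the
#' unattended one. Ties count as incorrect; a non-finite correlation
#' (degenerate reconstruction) is treated as \eqn{-\infty}.
#'
#' @param r_speaker1,r_speaker2 Pearson correlations of the reconstruction
#'   with speaker 1's and speaker 2's envelopes.
#' @param attended Attended speaker, 1 or 2.
#' @return Logical: decoded correctly?
#' @export
classify_trial <- function(r_speaker1, r_speaker2, attended) {
  if (!attended %in% c(1, 2)) abort("attended must be 1 or 2")
  r <- c(r_speaker1, r_speaker2)
  r[!is.finite(r)] <- -Inf
  r_att <- r[attended]
  r_unatt <- r[3 - attended]
  is.finite(r_att) && r_att > r_unatt
}

#' Leave-one-out cross-validated offline decoding
#'
#' For every held-out trial, one ridge decoder is fit per remaining trial
#' (against that trial's attended envelope), the weight arrays are averaged
#' elementwise with equal weights, the held-out trial's envelope is
#' reconstructed with the averaged decoder, and the reconstruction is
#' correlated (Pearson, full trial) with both speakers' envelopes.
#' Offline accuracy is the percentage of correctly classified trials.
#' Location-switching trials are not valid here and are rejected.
#'
#' @param trials A tibble with one row per location-fixed trial and columns
#'   `trial_id`, `attended_speaker`, plus list-columns `eeg` (raw
#'   [eeg_trial()] at `config$fs_acq`), `env1`, `env2` (standardized
#'   [envelope()]s at `config$fs_proc`) — the shape produced by
#'   [generate_dataset()].
#' @param config An [aad_config()].
#' @return An `aad_loocv` object: per-trial tibble (via [tidy()]) and the
#'   overall accuracy with its binomial chance level (via [glance()]).
#' @export
loocv_evaluate <- function(trials, config = aad_config()) {
  trials <- tibble::as_tibble(trials)
  if ("kind" %in% names(trials) && any(trials$kind != "fixed")) {
    abort("location-switching trials cannot enter the offline LOOCV; filter to kind == 'fixed'")
  }
  lags <- decoder_lags(config)
  fits <- vector("list", nrow(trials))
  keep <- rep(TRUE, nrow(trials))
  for (k in seq_len(nrow(trials))) {
    fits[[k]] <- tryCatch({
      proc <- preprocess_eeg(trials$eeg[[k]], config)
      design <- build_lagged_design(proc, lags)
      att_env <- if (trials$attended_speaker[k] == 1) trials$env1[[k]] else trials$env2[[k]]
      dec <- fit_ridge_decoder(design, att_env, config$lambda_reg)
      list(decoder = dec, design = design)
    }, error = function(e) {
      warn(sprintf("trial %s excluded: %s", trials$trial_id[k], conditionMessage(e)))
      NULL
    })
    keep[k] <- !is.null(fits[[k]])
  }
  trials <- trials[keep, ]
  fits <- fits[keep]
  n <- nrow(trials)
  if (n < 2) abort("need at least 2 usable location-fixed trials for LOOCV")
  w_sum <- Reduce(`+`, lapply(fits, function(f) f$decoder$weights))
  res <- vector("list", n)
  for (k in seq_len(n)) {
    # average of the decoders of all *other* trials
    w_avg <- (w_sum - fits[[k]]$decoder$weights) / (n - 1)
    dec <- new_decoder(w_avg, lambda = config$lambda_reg, lag_samples = lags,
                       fs = config$fs_proc,
                       channel_labels = fits[[k]]$decoder$channel_labels,
                       provenance = n - 1L)
    shat <- reconstruct_envelope(dec, fits[[k]]$design)$values
    r1 <- safe_cor(shat, trials$env1[[k]]$values)
    r2 <- safe_cor(shat, trials$env2[[k]]$values)
    att <- trials$attended_speaker[k]
    res[[k]] <- tibble::tibble(
      trial_id = trials$trial_id[k],
      attended_speaker = att,
      r1 = r1, r2 = r2,
      r_attended = if (att == 1) r1 else r2,
      r_unattended = if (att == 1) r2 else r1,
      correct = classify_trial(r1, r2, att)
    )
  }
  per_trial <- dplyr::bind_rows(res)
  structure(
    list(trials = per_trial,
         accuracy = 100 * mean(per_trial$correct),
         n_trials = n,
         chance_level = binomial_chance_level(n, 0.5),
         config = config),
    class = "aad_loocv"
  )
}

#' @export
print.aad_loocv <- function(x, ...) {
  cat(sprintf("<aad_loocv> offline decoding of %d location-fixed trials\n", x$n_trials))
  cat(sprintf("  accuracy     : %.2f %% (%d/%d trials)\n",
              x$accuracy, sum(x$trials$correct), x$n_trials))
  cat(sprintf("  chance level : %.2f %% (binomial, p0 = 0.5, 95%%)\n", x$chance_level))
  cat(sprintf("  mean r       : attended %.3f, unattended %.3f\n",
              mean(x$trials$r_attended), mean(x$trials$r_unattended)))
  invisible(x)
}

#' @describeIn loocv_evaluate per-trial correlations and classifications.
#' @param x An `aad_loocv` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.aad_loocv <- function(x, ...) x$trials

#' @describeIn loocv_evaluate one-row summary: accuracy, n, chance level,
#'   mean attended/unattended correlations.
#' @exportS3Method generics::glance
glance.aad_loocv <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_trials = x$n_trials,
    n_correct = sum(x$trials$correct),
    chance_level = x$chance_level,
    mean_r_attended = mean(x$trials$r_attended),
    mean_r_unattended = mean(x$trials$r_unattended)
  )
}

#' @describeIn fit_ridge_decoder decoder weights in long format:
#'   `lag`, `lag_ms`, `channel`, `weight`.
#' @param x An `aad_decoder`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.aad_decoder <- function(x, ...) {
  fs <- if (is.finite(x$fs)) x$fs else NA_real_
  tibble::tibble(
    lag = rep(x$lag_samples, times = ncol(x$weights)),
    lag_ms = rep(x$lag_samples / fs * 1000, times = ncol(x$weights)),
    channel = rep(x$channel_labels, each = nrow(x$weights)),
    weight = as.vector(x$weights)
  )
}

#' @describeIn fit_ridge_decoder one-row summary of a fitted decoder.
#' @exportS3Method generics::glance
glance.aad_decoder <- function(x, ...) {
  tibble::tibble(
    n_lags = nrow(x$weights),
    n_channels = ncol(x$weights),
    lambda = x$lambda,
    fs_proc = x$fs,
    weight_norm = sqrt(sum(x$weights^2)),
    provenance = x$provenance
  )
}
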