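# Statistical summaries: binomial chance levels for two-alternative
# classification, temporal sensitivity to spatial-attention switches, and
# mean +/- SEM tables.

#' Binomial chance level for a classification accuracy
#'
#' The smallest accuracy that a classifier must *strictly exceed* to be
#' called above chance: `100 * k / n` where k is the smallest integer with
#' \eqn{P(X \le k) \ge} `level` under Binomial(`n`, `p0`) (the inverse-CDF
#' convention). For 26 trials at p0 = 0.5 this is 17/26 = 65.38 %; for 60
#' questions at p0 = 0.25 it is 21/60 = 35 %.
#'
#' @param n Number of independent decisions.
#' @param p0 Null success probability.
#' @param level Confidence level, default 0.95.
#' @return Chance level in percent.
#' @export
#' @examples
#' binomial_chance_level(26, 0.5)   # 65.38...
#' binomial_chance_level(60, 0.25)  # 35
binomial_chance_level <- function(n, p0, level = 0.95) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("n must be a positive integer")
  }
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) abort("p0 must lie in (0, 1)")
  if (!is.numeric(level) || level <= 0 || level >= 1) abort("level must lie in (0, 1)")
  100 * stats::qbinom(level, n, p0) / n
}

#' Temporal sensitivity to a spatial attention switch
#'
#' Measures how quickly decoding becomes reliably correct again after the
#' attended talker's ear of presentation switches. Uses the *raw* (not
#' EMA-smoothed) per-window correlations: a post-switch window is correct
#' when the raw correlation with the attended speaker strictly exceeds the
#' unattended one. The response time is the time from the switch to the
#' start of the first run of at least `persistence_s` consecutive correct
#' windows (so a momentary lucky window does not count); if no such run
#' occurs before the trial ends, the response time is capped at the time
#' remaining after the switch (30 s for a mid-trial switch in a 60-s trial)
#' and flagged `capped`.
#'
#' @param trace An `aad_trace` for one switching trial (see
#'   [stream_decode()]); its `switch_time_s` column is used unless
#'   `switch_time_s` is supplied.
#' @param switch_time_s Switch time in seconds (overrides the trace column).
#' @param persistence_s Minimum persistence of correct decoding, default 5 s
#'   (at the 1-s step this is 5 consecutive windows, inclusive).
#' @param cap_s Cap value; defaults to trial end minus switch time.
#' @return A one-row tibble: `trial_id`, `response_time_s`, `capped`,
#'   `cap_value_s`.
#' @export
temporal_sensitivity <- function(trace, switch_time_s = NULL,
                                 persistence_s = 5, cap_s = NULL) {
  trace <- tibble::as_tibble(trace)
  if (is.null(switch_time_s)) {
    switch_time_s <- trace$switch_time_s[1]
  }
  if (is.null(switch_time_s) || is.na(switch_time_s)) {
    abort("no switch time available for this trace")
  }
  trial_end <- max(trace$window_end_s)
  if (switch_time_s <= 0 || switch_time_s >= trial_end) {
    abort("switch time lies outside the trial")
  }
  step <- if (nrow(trace) > 1) diff(trace$window_end_s[1:2]) else 1
  post <- trace[trace$window_end_s > switch_time_s, ]
  if (nrow(post) == 0) abort("trace has no windows past the switch time")
  att <- post$attended_speaker[1]
  r_att <- if (att == 1) post$r1_raw else post$r2_raw
  r_un <- if (att == 1) post$r2_raw else post$r1_raw
  ok <- is.finite(r_att) & is.finite(r_un) & (r_att > r_un)
  n_req <- ceiling(persistence_s / step)
  cap_value <- cap_s %||% (trial_end - switch_time_s)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= n_req)
  if (length(hit) == 0) {
    rt <- cap_value
    capped <- TRUE
  } else {
    rt <- starts[hit[1]] * step
    capped <- FALSE
  }
  tibble::tibble(
    trial_id = trace$trial_id[1] %||% "trial",
    response_time_s = rt,
    capped = capped,
    cap_value_s = cap_value
  )
}

#' Mean and standard error of a set of values
#'
#' @param x Numeric vector (e.g. per-subject or per-trial accuracies).
#' @return A one-row tibble: `mean`, `sem` (`sd/sqrt(n)`; 0 with
#'   `single_value = TRUE` when n = 1), `n`, `single_value`.
#' @export
#' @examples
#' mean_sem(c(70, 80, 90))
mean_sem <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || all(is.na(x))) abort("no values to summarize")
  x <- x[!is.na(x)]
  n <- length(x)
  tibble::tibble(
    mean = mean(x),
    sem = if (n > 1) stats::sd(x) / sqrt(n) else 0,
    n = n,
    single_value = n == 1
  )
}

#' Mean +/- SEM summary table split by group
#'
#' @param data A data frame.
#' @param value Column to summarize (tidy-eval).
#' @param by Optional grouping column (tidy-eval), e.g. trial kind.
#' @return A tibble with one row per group (plus columns from [mean_sem()]).
#' @export
summarize_results <- function(data, value, by = NULL) {
  value <- rlang::enquo(value)
  by <- rlang::enquo(by)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("no results to summarize")
  if (rlang::quo_is_null(by)) {
    return(mean_sem(rlang::eval_tidy(value, data)))
  }
  data |>
    dplyr::group_by(!!by) |>
    dplyr::summarise(mean_sem(!!value), .groups = "drop")
}
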