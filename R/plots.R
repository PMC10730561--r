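# ggplot2 views of the main result objects.

#' Plot a real-time correlation trace
#'
#' Raw and EMA-smoothed envelope correlations for both speakers over the
#' sliding windows of one (or several faceted) trials; a dashed vertical
#' line marks the attention switch where present.
#'
#' @param object An `aad_trace` from [stream_decode()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aad_trace <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = c("r1_raw", "r2_raw", "r1_ema", "r2_ema"),
                        names_to = c("speaker", "smoothing"),
                        names_pattern = "r([12])_(raw|ema)",
                        values_to = "r") |>
    dplyr::mutate(
      speaker = paste("speaker", .data$speaker),
      smoothing = factor(.data$smoothing, c("raw", "ema"),
                         c("raw", "EMA-smoothed"))
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$window_end_s, .data$r,
                                        colour = .data$speaker)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window end time (s)", y = "envelope correlation r",
                  colour = NULL)
  sw <- unique(stats::na.omit(object$switch_time_s))
  if (length(sw)) {
    p <- p + ggplot2::geom_vline(xintercept = sw, linetype = "dashed")
  }
  if (dplyr::n_distinct(df$trial_id) > 1) {
    p + ggplot2::facet_grid(rows = ggplot2::vars(.data$smoothing),
                            cols = ggplot2::vars(.data$trial_id))
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$smoothing), ncol = 1)
  }
}

#' Plot decoder weights
#'
#' Heatmap of the backward-model weights over time lag and channel.
#'
#' @param object An `aad_decoder`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aad_decoder <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(channel = factor(.data$channel, unique(.data$channel)))
  xvar <- if (all(is.finite(df$lag_ms))) "lag_ms" else "lag"
  ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$channel,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = if (xvar == "lag_ms") "time lag (ms)" else "time lag (samples)",
                  y = NULL, fill = "weight")
}

#' Plot offline LOOCV results
#'
#' Attended vs unattended envelope correlations per trial; points above the
#' identity line are correctly decoded trials.
#'
#' @param object An `aad_loocv` from [loocv_evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aad_loocv <- function(object, ...) {
  ggplot2::ggplot(object$trials,
                  ggplot2::aes(.data$r_unattended, .data$r_attended,
                               colour = .data$correct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "r with unattended envelope", y = "r with attended envelope",
      colour = "correct",
      title = sprintf("offline LOOCV accuracy %.1f %% (chance %.2f %%)",
                      object$accuracy, object$chance_level))
}
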