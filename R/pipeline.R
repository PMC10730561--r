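# Orchestration: simulate -> offline LOOCV -> real-time streaming ->
# temporal sensitivity, bundled into a reproducible report.

#' Published real-EEG reference benchmarks
#'
#' Mean +/- SEM performance reported by the nine-subject validation study
#' of this protocol on real EEG, for context when reading synthetic-data
#' reports. These numbers depend on real subjects' brains and are *not*
#' reproduced by the synthetic pipeline; they are displayed for reference
#' only.
#'
#' @return A tibble with columns `measure`, `mean`, `sem`, `unit`.
#' @export
aad_reference <- function() {
  tibble::tribble(
    ~measure,                        ~mean, ~sem,  ~unit,
    "offline accuracy",              90.60, 3.34,  "%",
    "real-time accuracy (all)",      78.37, 2.03,  "%",
    "real-time accuracy (fixed)",    79.92, 3.36,  "%",
    "real-time accuracy (switching)", 73.67, 5.27, "%",
    "temporal sensitivity",          7.97,  1.56,  "s"
  )
}

#' Offline evaluation stage
#'
#' Filters the dataset to location-fixed trials and runs the leave-one-out
#' cross-validated offline decoder ([loocv_evaluate()]).
#'
#' @param dataset An `aad_dataset` (tibble) or a directory path written by
#'   [write_dataset()].
#' @param config An [aad_config()].
#' @return The `aad_loocv` result.
#' @export
run_offline <- function(dataset, config = aad_config()) {
  dataset <- as_dataset(dataset)
  fixed <- dataset[dataset$kind == "fixed", ]
  if (nrow(fixed) < 2) abort("offline evaluation needs at least 2 location-fixed trials")
  loocv_evaluate(fixed, config)
}

#' Real-time evaluation stage
#'
#' Trains the streaming decoder on the first `n_train` location-fixed
#' trials and stream-decodes the remaining trials (the later fixed trials
#' plus all switching trials). Reports pooled and split window accuracies
#' and the temporal sensitivity of each switching trial.
#'
#' @param dataset An `aad_dataset` or a directory path.
#' @param config An [aad_config()].
#' @param n_train Training-set size (default 14 location-fixed trials).
#' @return An `aad_realtime` object: trained decoder, bound traces,
#'   accuracy table and sensitivity table.
#' @export
run_realtime <- function(dataset, config = aad_config(), n_train = 14) {
  dataset <- as_dataset(dataset)
  fixed_idx <- which(dataset$kind == "fixed")
  if (length(fixed_idx) < n_train + 1) {
    abort(sprintf("need at least %d location-fixed trials (%d for training plus tests); found %d",
                  n_train + 1, n_train, length(fixed_idx)))
  }
  train_idx <- fixed_idx[seq_len(n_train)]
  test_idx <- setdiff(seq_len(nrow(dataset)), train_idx)
  decoder <- train_realtime_decoder(dataset[train_idx, ], config)
  traces <- purrr::map(test_idx, function(k) {
    stream_decode(dataset$eeg[[k]], dataset$env1[[k]], dataset$env2[[k]],
                  decoder, config, metadata = dataset[k, ])
  })
  all_traces <- dplyr::bind_rows(traces)
  sens_rows <- purrr::map(traces[dataset$kind[test_idx] == "switching"],
                          temporal_sensitivity)
  sensitivity <- if (length(sens_rows)) dplyr::bind_rows(sens_rows) else
    tibble::tibble(trial_id = character(), response_time_s = numeric(),
                   capped = logical(), cap_value_s = numeric())
  structure(
    list(decoder = decoder,
         traces = all_traces,
         accuracy = window_accuracy(all_traces),
         sensitivity = sensitivity,
         n_train = n_train,
         n_test = length(test_idx),
         config = config),
    class = "aad_realtime"
  )
}

#' @export
print.aad_realtime <- function(x, ...) {
  cat(sprintf("<aad_realtime> trained on %d trials (%d snippet decoders), %d test trials\n",
              x$n_train, x$decoder$provenance, x$n_test))
  acc <- x$accuracy
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-10s : %6.2f %% over %d windows (%d trials)\n",
                acc$kind[i], acc$accuracy[i], acc$n_windows[i], acc$n_trials[i]))
  }
  if (nrow(x$sensitivity)) {
    s <- mean_sem(x$sensitivity$response_time_s)
    cat(sprintf("  sensitivity: %.2f +/- %.2f s over %d switching trials (%d capped)\n",
                s$mean, s$sem, s$n, sum(x$sensitivity$capped)))
  }
  invisible(x)
}

#' @describeIn run_realtime the pooled per-window trace tibble.
#' @param x An `aad_realtime` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.aad_realtime <- function(x, ...) x$traces

#' @describeIn run_realtime one-row summary of real-time performance.
#' @exportS3Method generics::glance
glance.aad_realtime <- function(x, ...) {
  get_acc <- function(k) {
    v <- x$accuracy$accuracy[x$accuracy$kind == k]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    accuracy_all = get_acc("all"),
    accuracy_fixed = get_acc("fixed"),
    accuracy_switching = get_acc("switching"),
    n_windows = x$accuracy$n_windows[x$accuracy$kind == "all"],
    n_train = x$n_train,
    n_test = x$n_test,
    mean_sensitivity_s = if (nrow(x$sensitivity)) mean(x$sensitivity$response_time_s) else NA_real_
  )
}

as_dataset <- function(dataset) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  tibble::as_tibble(dataset)
}

#' Run the full synthetic experiment
#'
#' Generates a dataset ([generate_dataset()]), evaluates the offline
#' decoder ([run_offline()]) and the simulated real-time decoder
#' ([run_realtime()]), and bundles everything into a report. With a fixed
#' seed the report is fully reproducible.
#'
#' @param config An [aad_config()].
#' @param seed Integer seed for dataset generation.
#' @param out_dir Optional directory; when given, the report tables
#'   (`report.tsv`, `windows.tsv`, `sensitivity.tsv`, `offline_trials.tsv`,
#'   `decoder_realtime.tsv`) are written there.
#' @param dataset Optional pre-generated `aad_dataset` (skips generation).
#' @param n_train Real-time training-set size.
#' @param ... Passed to [generate_dataset()] (e.g. `noise_sd`, gain
#'   parameters, `n_trials`).
#' @return An `aad_report` object.
#' @export
run_all <- function(config = aad_config(), seed = 1, out_dir = NULL,
                    dataset = NULL, n_train = 14, ...) {
  if (is.null(dataset)) {
    dataset <- generate_dataset(config, seed = seed, n_train = n_train, ...)
  }
  offline <- run_offline(dataset, config)
  realtime <- run_realtime(dataset, config, n_train = n_train)
  report <- structure(
    list(offline = offline, realtime = realtime, config = config,
         seed = seed,
         n_trials = nrow(dataset),
         version = as.character(utils::packageVersion("aadkit"))),
    class = "aad_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(glance(report), file.path(out_dir, "report.tsv"))
  write_results(report$realtime$traces, file.path(out_dir, "windows.tsv"))
  if (nrow(report$realtime$sensitivity)) {
    write_results(report$realtime$sensitivity,
                  file.path(out_dir, "sensitivity.tsv"))
  }
  write_results(tidy(report$offline), file.path(out_dir, "offline_trials.tsv"))
  write_decoder(report$realtime$decoder,
                file.path(out_dir, "decoder_realtime.tsv"))
  invisible(out_dir)
}

#' @export
print.aad_report <- function(x, ...) {
  cat(sprintf("== AAD synthetic experiment report (seed %d, aadkit %s) ==\n",
              x$seed, x$version))
  cat(sprintf("dataset: %d trials, %d used offline, %d train / %d test real-time\n",
              x$n_trials, x$offline$n_trials, x$realtime$n_train, x$realtime$n_test))
  cat("\n-- offline decoder (leave-one-out CV) --\n")
  print(x$offline)
  cat("\n-- real-time decoder (sliding window + EMA) --\n")
  print(x$realtime)
  cat("\n-- reference values from the real-EEG validation study (context only) --\n")
  ref <- aad_reference()
  for (i in seq_len(nrow(ref))) {
    cat(sprintf("  %-28s %6.2f +/- %.2f %s\n",
                ref$measure[i], ref$mean[i], ref$sem[i], ref$unit[i]))
  }
  invisible(x)
}

#' @describeIn run_all one-row summary of all report quantities.
#' @param x An `aad_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.aad_report <- function(x, ...) {
  rt <- glance(x$realtime)
  tibble::tibble(
    offline_accuracy = x$offline$accuracy,
    offline_n_trials = x$offline$n_trials,
    offline_chance_level = x$offline$chance_level,
    realtime_accuracy_all = rt$accuracy_all,
    realtime_accuracy_fixed = rt$accuracy_fixed,
    realtime_accuracy_switching = rt$accuracy_switching,
    realtime_n_windows = rt$n_windows,
    mean_sensitivity_s = rt$mean_sensitivity_s,
    seed = x$seed
  )
}
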