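# Orchestration: run one or several detectors on a recording or a simulated
# batch and score them against ground truth.

#' Names of the available detection algorithms
#' @return Character vector of valid `algorithm` values.
#' @export
wear_algorithms <- function() {
  c(
    "accel",
    "temp-window-fixed", "temp-window-adaptive",
    "temp-event-a", "temp-event-b", "temp-event-c", "temp-event-d",
    "combined"
  )
}

default_run_params <- function() {
  list(
    epoch_s = 60,
    accel = list(fc1 = 0.5, fc2 = 20, order = 4, thr_g = 0.013,
                 min_nonwear_s = 1800),
    temp = list(factor = 6, sg_window = 11, sg_polyorder = 3),
    window = list(base_c = 18, window_s = 60),
    event = event_params(),
    combined_option = "d"
  )
}

merge_params <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run one or more detectors on a recording
#'
#' Shares the preprocessing (band-passed vector magnitude SD; downsampled +
#' smoothed temperature) across algorithms.
#'
#' @param rec A `wear_recording`.
#' @param algorithms Subset of [wear_algorithms()].
#' @param params Optional nested list overriding [default parameters]
#'   (epoch length, filter cutoffs, thresholds, event parameters).
#' @return Named list of `wear_epochs`, one per algorithm.
#' @export
detect_wear <- function(rec, algorithms = "temp-event-d", params = list()) {
  bad <- setdiff(algorithms, wear_algorithms())
  if (length(bad)) {
    stop_config(sprintf(
      "unknown algorithm(s): %s. Valid names: %s",
      paste(bad, collapse = ", "), paste(wear_algorithms(), collapse = ", ")
    ))
  }
  p <- merge_params(default_run_params(), params)
  need_accel <- any(algorithms %in% c("accel", "combined"))
  need_temp <- any(grepl("^temp-", algorithms)) || "combined" %in% algorithms
  combined_algo <- paste0("temp-event-", p$combined_option)

  sdser <- NULL
  if (need_accel) {
    sdser <- rec |>
      vm_dynamic(p$accel$fc1, p$accel$fc2, p$accel$order) |>
      windowed_std(window_s = p$epoch_s)
  }
  ts <- NULL
  if (need_temp) {
    ts <- preprocess_temp(rec, p$temp$factor, p$temp$sg_window,
                          p$temp$sg_polyorder)
  }

  run_one <- function(algo) {
    switch(algo,
      "accel" = detect_accel(sdser, p$accel$thr_g, p$accel$min_nonwear_s),
      "temp-window-fixed" = detect_window(
        ts, fixed_threshold(p$window$base_c), p$window$window_s
      ),
      "temp-window-adaptive" = detect_window(
        ts, adaptive_threshold(ts, p$window$base_c), p$window$window_s
      ),
      "temp-event-a" = ,
      "temp-event-b" = ,
      "temp-event-c" = ,
      "temp-event-d" = detect_event(
        ts, p$event, option = sub("temp-event-", "", algo),
        epoch_s = p$epoch_s, duration_s = rec$duration_s,
        sg_window = p$temp$sg_window, sg_polyorder = p$temp$sg_polyorder
      )$epochs,
      "combined" = NULL
    )
  }
  out <- list()
  for (algo in setdiff(algorithms, "combined")) out[[algo]] <- run_one(algo)
  if ("combined" %in% algorithms) {
    acc_e <- out[["accel"]] %||% run_one("accel")
    temp_e <- out[[combined_algo]] %||% run_one(combined_algo)
    out[["combined"]] <- combine_and(acc_e, temp_e)
  }
  out[algorithms]
}

#' Evaluate detectors over a batch of simulated recordings
#'
#' Lower-level engine behind [run_compare()] that also collects the
#' quantities used to validate the event-based detector at protocol scale:
#' the timing error of every detected removal/reattachment boundary against
#' the nearest true non-wear boundary, and where the accelerometer
#' detector's false-negative epochs (true wear called non-wear) fall
#' relative to the simulated sleep blocks. Recordings are simulated,
#' processed and discarded one at a time, so memory stays flat.
#'
#' @param scenarios List of [sim_scenario()] objects (see
#'   [protocol_scenarios()]).
#' @param algorithms Subset of [wear_algorithms()].
#' @param pocket_as Ground-truth scoring of pocket intervals (see
#'   [intervals_to_epochs()]).
#' @param params Detector parameter overrides (see [detect_wear()]).
#' @return A list: `per_recording` (metrics per recording and algorithm),
#'   `boundaries` (one row per detected event-based boundary with its error
#'   in seconds), `accel_fn` (per recording: false-negative epoch count and
#'   how many fall inside sleep), `detect_elapsed_s` (processing time spent
#'   in the detectors, excluding simulation).
#' @export
evaluate_batch <- function(scenarios, algorithms = "temp-event-d",
                           pocket_as = "wear", params = list()) {
  need_acc <- any(algorithms %in% c("accel", "combined"))
  event_algo <- grep("^temp-event-", algorithms, value = TRUE)
  per <- vector("list", length(scenarios))
  bounds <- list()
  fnrows <- list()
  t_detect <- 0
  for (i in seq_along(scenarios)) {
    sim <- simulate_recording(scenarios[[i]],
      channels = if (need_acc) "full" else "temp"
    )
    dur <- sim$recording$duration_s
    truth <- intervals_to_epochs(sim$truth, dur, pocket_as = pocket_as)
    t0 <- proc.time()[[3L]]
    eps <- detect_wear(sim$recording, algorithms, params)
    t_detect <- t_detect + proc.time()[[3L]] - t0
    per[[i]] <- bind_rows(lapply(names(eps), function(a) {
      mutate(as_tibble(confusion(eps[[a]], truth)),
        recording = i, algorithm = a, .before = 1L
      )
    }))
    if (length(event_algo)) {
      det_iv <- epochs_to_intervals(eps[[event_algo[1L]]])
      true_b <- sim$truth[sim$truth$label == "nonwear", ]
      true_bounds <- c(true_b$start_s, true_b$end_s)
      if (nrow(det_iv)) {
        det_bounds <- c(det_iv$start_s, det_iv$end_s)
        err <- vapply(det_bounds, function(b) {
          if (length(true_bounds)) min(abs(b - true_bounds)) else Inf
        }, numeric(1))
        bounds[[length(bounds) + 1L]] <- tibble(
          recording = i, boundary_s = det_bounds, error_s = err
        )
      }
    }
    if ("accel" %in% algorithms) {
      fn_mask <- eps[["accel"]]$label == 1L & truth$label == 0L & !truth$mask
      mid <- eps[["accel"]]$time_s + epoch_s_of(eps[["accel"]]) / 2
      in_sleep <- rep(FALSE, length(mid))
      for (j in seq_len(nrow(sim$sleep))) {
        in_sleep <- in_sleep |
          (mid > sim$sleep$start_s[j] & mid < sim$sleep$end_s[j])
      }
      fnrows[[length(fnrows) + 1L]] <- tibble(
        recording = i,
        fn = sum(fn_mask),
        fn_in_sleep = sum(fn_mask & in_sleep)
      )
    }
    rm(sim, eps)
    gc(FALSE)
  }
  list(
    per_recording = bind_rows(per),
    boundaries = bind_rows(bounds),
    accel_fn = bind_rows(fnrows),
    detect_elapsed_s = t_detect
  )
}

#' Compare algorithms on a simulated protocol batch
#'
#' Simulates `n` recordings, runs each requested algorithm, scores it
#' against the schedule-derived ground truth on the common epoch grid, and
#' aggregates the metrics across recordings (mean and SD per metric).
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `n` (recordings, default 16), `seed` (default 1), `algorithms`
#'   (default all), `pocket_as` (`"wear"`, `"nonwear"` or `"exclude"`),
#'   `scenario` (overrides passed to [sim_scenario()]), `params` (detector
#'   overrides, see [detect_wear()]), `out` (optional output directory:
#'   config, per-recording and summary CSVs and a comparison figure are
#'   written there).
#' @return An object of class `wear_comparison`: list with `per_recording`
#'   (tibble: recording, algorithm, counts and metrics), `summary` (tibble:
#'   algorithm, metric, mean, sd, n) and `config`. `tidy()` returns the
#'   per-recording table, `autoplot()` a grouped bar chart of the summary.
#' @export
run_compare <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  n <- config$n %||% 16L
  seed <- config$seed %||% 1L
  algorithms <- config$algorithms %||% wear_algorithms()
  pocket_as <- config$pocket_as %||% "wear"
  if (!is_count(n) || !is_count(seed)) {
    stop_config("config$n and config$seed must be positive integers")
  }
  bad <- setdiff(algorithms, wear_algorithms())
  if (length(bad)) {
    stop_config(sprintf(
      "unknown algorithm(s): %s. Valid names: %s",
      paste(bad, collapse = ", "), paste(wear_algorithms(), collapse = ", ")
    ))
  }
  params <- config$params %||% list()
  epoch_s <- merge_params(default_run_params(), params)$epoch_s
  scenarios <- do.call(
    protocol_scenarios,
    c(list(n = n, seed = seed), config$scenario %||% list())
  )
  need_acc <- any(algorithms %in% c("accel", "combined"))
  per <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_recording(scenarios[[i]],
      channels = if (need_acc) "full" else "temp"
    )
    truth <- intervals_to_epochs(sim$truth, sim$recording$duration_s,
      epoch_s = epoch_s, pocket_as = pocket_as
    )
    eps <- detect_wear(sim$recording, algorithms, params)
    per[[i]] <- bind_rows(lapply(names(eps), function(a) {
      mutate(as_tibble(confusion(eps[[a]], truth)),
        recording = i, algorithm = a, .before = 1L
      )
    }))
    rm(sim, eps)
  }
  per <- bind_rows(per)
  summary <- per |>
    group_by(.data$algorithm) |>
    dplyr::group_modify(~ aggregate_metrics(.x)) |>
    ungroup()
  res <- structure(
    list(per_recording = per, summary = summary,
         config = list(n = n, seed = seed, algorithms = algorithms,
                       pocket_as = pocket_as,
                       scenario = config$scenario %||% list(),
                       params = params)),
    class = "wear_comparison"
  )
  if (!is.null(config$out)) write_comparison(res, config$out)
  res
}

write_comparison <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(res$config, file.path(dir, "config.yaml"))
  readr::write_csv(res$per_recording, file.path(dir, "metrics_per_recording.csv"))
  readr::write_csv(res$summary, file.path(dir, "metrics_summary.csv"))
  ggplot2::ggsave(
    file.path(dir, "comparison.pdf"), autoplot(res),
    width = 9, height = 5
  )
  invisible(dir)
}

#' @export
print.wear_comparison <- function(x, ...) {
  cat(sprintf(
    "<wear_comparison> %d algorithm(s) x %d recording(s), seed %d\n",
    length(unique(x$per_recording$algorithm)),
    x$config$n, x$config$seed
  ))
  wide <- tidyr::pivot_wider(
    select(x$summary, "algorithm", "metric", "mean"),
    names_from = "metric", values_from = "mean"
  )
  print(wide)
  invisible(x)
}

#' @describeIn run_compare Per-recording metric table.
#' @param x A `wear_comparison`.
#' @param ... Unused.
#' @export
tidy.wear_comparison <- function(x, ...) x$per_recording

#' @describeIn run_compare Aggregated summary table.
#' @export
glance.wear_comparison <- function(x, ...) x$summary
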