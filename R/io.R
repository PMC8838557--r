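# Reading and writing sensor time series and interval annotations.
#
# CSV dialect: comma-separated, header row, '.' decimal, UTF-8.
#   acceleration: time_s, ax_g, ay_g, az_g   (units g)
#   temperature:  time_s, temp_c             (degrees Celsius)
#   intervals:    start_s, end_s, label      (wear / nonwear / pocket)

read_channel_csv <- function(path, cols) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop_format(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  if (!nrow(x)) stop_data(sprintf("%s: file has no data rows", path))
  x[cols]
}

check_time_axis <- function(time_s, fs, what) {
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stop_data(sprintf(
      "%s: time not strictly increasing at row %d (t = %g s)",
      what, i + 1L, time_s[i + 1L]
    ))
  }
  gaps <- which(dt > 2 / fs)
  if (length(gaps)) {
    i <- gaps[1L]
    stop_data(sprintf(
      "%s: gap of %.3f s between t = %g s and t = %g s (max allowed %g s)",
      what, dt[i], time_s[i], time_s[i + 1L], 2 / fs
    ))
  }
  invisible(TRUE)
}

new_recording <- function(acc, fs_acc, temp, fs_temp, t0, duration_s,
                          meta = list()) {
  structure(
    list(
      acc = acc, fs_acc = fs_acc,
      temp = temp, fs_temp = fs_temp,
      t0 = t0, duration_s = duration_s, meta = meta
    ),
    class = "wear_recording"
  )
}

#' Read a synchronized acceleration + temperature recording
#'
#' Reads the two channel CSVs, validates monotone time axes (gaps larger than
#' two sample periods are an error), trims both channels to their common time
#' span, and re-expresses time as seconds from the common origin.
#'
#' Internally the acceleration channel is stored without an explicit time
#' column (time is implicit from `t0` and `fs_acc`), which keeps multi-day
#' 100 Hz recordings manageable in memory.
#'
#' @param acc_path CSV with columns `time_s, ax_g, ay_g, az_g`.
#' @param temp_path CSV with columns `time_s, temp_c`.
#' @param fs_acc,fs_temp Nominal sampling rates in Hz.
#' @return A `wear_recording`: list with `acc` (tibble `ax_g, ay_g, az_g`),
#'   `temp` (tibble `time_s, temp_c`, time relative to `t0`), `fs_acc`,
#'   `fs_temp`, `t0`, `duration_s`.
#' @export
read_recording <- function(acc_path, temp_path, fs_acc = 100, fs_temp = 1) {
  acc <- read_channel_csv(acc_path, c("time_s", "ax_g", "ay_g", "az_g"))
  temp <- read_channel_csv(temp_path, c("time_s", "temp_c"))
  check_time_axis(acc$time_s, fs_acc, basename(acc_path))
  check_time_axis(temp$time_s, fs_temp, basename(temp_path))
  if (any(!is.finite(as.matrix(acc[-1L])))) {
    stop_data("acceleration values must be finite")
  }
  if (any(!is.finite(temp$temp_c)) ||
      any(temp$temp_c < -40 | temp$temp_c > 60)) {
    stop_data("temperature values must be finite and within [-40, 60] degC")
  }

  t0 <- max(acc$time_s[1L], temp$time_s[1L])
  t_end <- min(
    acc$time_s[nrow(acc)] + 1 / fs_acc,
    temp$time_s[nrow(temp)] + 1 / fs_temp
  )
  if (t_end <= t0) stop_data("channels have no common time span")
  acc <- acc[acc$time_s >= t0 & acc$time_s < t_end, ]
  temp <- temp[temp$time_s >= t0 & temp$time_s < t_end, ]

  new_recording(
    acc = as_tibble(acc[c("ax_g", "ay_g", "az_g")]),
    fs_acc = fs_acc,
    temp = tibble(time_s = temp$time_s - t0, temp_c = temp$temp_c),
    fs_temp = fs_temp,
    t0 = t0,
    duration_s = t_end - t0
  )
}

#' Read interval annotations
#'
#' @param path CSV with columns `start_s, end_s, label`.
#' @return Validated tibble of half-open, sorted, non-overlapping intervals.
#' @export
read_intervals <- function(path) {
  x <- read_channel_csv(path, c("start_s", "end_s", "label"))
  validate_intervals(x)
}

#' Write interval annotations
#' @param intervals Tibble with `start_s, end_s, label`.
#' @param path Output CSV path.
#' @export
write_intervals <- function(intervals, path) {
  readr::write_csv(validate_intervals(intervals), path)
  invisible(path)
}

#' Write epoch labels
#' @param epochs A `wear_epochs` tibble.
#' @param path Output CSV path.
#' @export
write_epochs <- function(epochs, path) {
  readr::write_csv(as_tibble(epochs), path)
  invisible(path)
}

#' Write a recording to the package CSV formats
#' @param rec A `wear_recording`.
#' @param acc_path,temp_path Output CSV paths.
#' @export
write_recording <- function(rec, acc_path, temp_path) {
  n <- nrow(rec$acc)
  acc <- tibble(
    time_s = rec$t0 + (seq_len(n) - 1L) / rec$fs_acc,
    ax_g = rec$acc$ax_g, ay_g = rec$acc$ay_g, az_g = rec$acc$az_g
  )
  readr::write_csv(acc, acc_path)
  temp <- tibble(time_s = rec$t0 + rec$temp$time_s, temp_c = rec$temp$temp_c)
  readr::write_csv(temp, temp_path)
  invisible(c(acc_path, temp_path))
}

#' @export
print.wear_recording <- function(x, ...) {
  cat(sprintf(
    "<wear_recording> %.1f h, accel %s @ %g Hz, temp %d samples @ %g Hz\n",
    x$duration_s / 3600,
    if (is.null(x$acc)) "absent" else format(nrow(x$acc), big.mark = ","),
    x$fs_acc, nrow(x$temp), x$fs_temp
  ))
  invisible(x)
}
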