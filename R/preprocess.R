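# Derived signals consumed by the detectors: band-passed vector magnitude,
# its windowed standard deviation, and the downsampled + smoothed temperature
# with its first derivative.

#' Dynamic (gravity-removed) vector magnitude
#'
#' Computes the Euclidean norm of the three acceleration axes and band-passes
#' it with a Butterworth filter (default 4th order, 0.5-20 Hz). The band-pass
#' removes the static gravity component, so the output indexes body movement
#' only. Filtering is applied zero-phase (forward-backward) so activity
#' transitions are not lagged.
#'
#' @param rec A `wear_recording`.
#' @param fc1,fc2 Lower / upper cut-off frequencies in Hz.
#' @param order Butterworth filter order.
#' @return A tibble of class `wear_signal` with column `vm_g` and attributes
#'   `fs`, `t0`.
#' @export
vm_dynamic <- function(rec, fc1 = 0.5, fc2 = 20, order = 4) {
  fs <- rec$fs_acc
  if (!is_number(fc1) || !is_number(fc2) || fc1 <= 0 || fc2 <= fc1) {
    stop_config("need 0 < fc1 < fc2")
  }
  if (fc2 >= fs / 2) {
    stop_config(sprintf(
      "fc2 = %g Hz must be below the Nyquist frequency %g Hz", fc2, fs / 2
    ))
  }
  if (is.null(rec$acc)) stop_data("recording has no acceleration channel")
  bf <- signal::butter(order, c(fc1, fc2) / (fs / 2), type = "pass")
  nf <- max(length(bf$b), length(bf$a))
  nfact <- 3L * (nf - 1L)
  n <- nrow(rec$acc)
  if (n <= nfact) stop_data("acceleration channel too short to filter")
  b <- c(bf$b, rep(0, nf - length(bf$b))) / bf$a[1L]
  a <- c(bf$a, rep(0, nf - length(bf$a))) / bf$a[1L]
  # padded VM buffer built and filtered without intermediate copies
  ext <- vm3_padded_cpp(rec$acc$ax_g, rec$acc$ay_g, rec$acc$az_g, nfact)
  ext <- filtfilt_cpp(b, a, ext, lfilter_zi(b, a))
  out <- tibble(vm_g = ext[(nfact + 1L):(nfact + n)])
  structure(out,
    fs = fs, t0 = rec$t0,
    class = c("wear_signal", class(out))
  )
}

#' Windowed standard deviation
#'
#' Population standard deviation (denominator n) of a signal over
#' non-overlapping windows; the trailing partial window is dropped. At 6000
#' samples per 1-min window the n vs n-1 distinction is negligible, but it is
#' fixed here for exactness.
#'
#' @param sig A `wear_signal` tibble (or numeric vector, with `fs` supplied).
#' @param window_s Window length in seconds.
#' @param fs Sampling rate in Hz; taken from `sig` when it is a
#'   `wear_signal`.
#' @return A tibble of class `wear_vmstd` with columns `time_s` (window
#'   start), `sd_g`, and attributes `window_s`, `t0`.
#' @export
windowed_std <- function(sig, window_s = 60, fs = NULL) {
  if (inherits(sig, "wear_signal")) {
    fs <- attr(sig, "fs")
    t0 <- attr(sig, "t0") %||% 0
    x <- sig$vm_g
  } else {
    if (is.null(fs)) stop_config("fs must be supplied for a plain vector")
    t0 <- 0
    x <- as.numeric(sig)
  }
  m <- round(fs * window_s)
  if (m < 2) stop_config("window must contain at least 2 samples")
  k <- floor(length(x) / m)
  if (k == 0L) {
    warn("signal shorter than one window; returning empty series")
    vals <- numeric(0)
  } else {
    vals <- windowed_sd_cpp(x, m)
  }
  out <- tibble(
    time_s = (seq_len(k) - 1L) * window_s,
    sd_g = vals
  )
  structure(out,
    window_s = window_s, t0 = t0,
    class = c("wear_vmstd", class(out))
  )
}

new_temp_series <- function(time_s, temp_c, dt_s, smoothed, t0 = 0) {
  out <- tibble(time_s = time_s, temp_c = temp_c)
  structure(out,
    dt_s = dt_s, smoothed = smoothed, t0 = t0,
    class = c("wear_temp", class(out))
  )
}

#' Extract the temperature channel of a recording
#' @param rec A `wear_recording`.
#' @return A tibble of class `wear_temp` with columns `time_s`, `temp_c` and
#'   attributes `dt_s`, `smoothed`, `t0`.
#' @export
temp_series <- function(rec) {
  new_temp_series(rec$temp$time_s, rec$temp$temp_c,
    dt_s = 1 / rec$fs_temp, smoothed = FALSE, t0 = rec$t0
  )
}

#' Downsample a temperature series
#'
#' Keeps every `factor`-th sample (the first, then every `factor` after it).
#' The temperature sensor's thermal response is slow relative to its sampling
#' rate, so decimation discards quantisation chatter without losing the
#' removal/reattachment transients; it also concentrates a transition's
#' temperature change into fewer samples, enhancing the derivative peaks the
#' event-based detector relies on.
#'
#' @param ts A `wear_temp` tibble.
#' @param factor Integer decimation factor (default 6).
#' @return A `wear_temp` tibble with `dt_s` multiplied by `factor`.
#' @export
downsample_temp <- function(ts, factor = 6) {
  if (!is_count(factor)) stop_config("factor must be a positive integer")
  idx <- seq(1L, nrow(ts), by = factor)
  new_temp_series(ts$time_s[idx], ts$temp_c[idx],
    dt_s = attr(ts, "dt_s") * factor,
    smoothed = attr(ts, "smoothed"), t0 = t0_of(ts)
  )
}

#' Savitzky-Golay smoothing of a temperature series
#'
#' Local polynomial least-squares smoothing, chosen because it suppresses
#' sensor noise while preserving the sudden level changes that mark device
#' removal/reattachment: any signal that is locally a polynomial of degree
#' `<= polyorder` passes through unchanged.
#'
#' @param ts A `wear_temp` tibble.
#' @param window_samples Odd filter window length in samples.
#' @param polyorder Polynomial degree, `< window_samples`.
#' @return A smoothed `wear_temp` tibble.
#' @export
smooth_temp <- function(ts, window_samples = 11, polyorder = 3) {
  if (!is_count(window_samples) || window_samples %% 2 == 0) {
    stop_config("window_samples must be an odd positive integer")
  }
  if (!is_count(polyorder + 1) || polyorder >= window_samples) {
    stop_config("polyorder must be a non-negative integer < window_samples")
  }
  if (window_samples > nrow(ts)) {
    stop_config("smoothing window longer than the series")
  }
  sm <- signal::sgolayfilt(ts$temp_c, p = polyorder, n = window_samples)
  new_temp_series(ts$time_s, sm,
    dt_s = attr(ts, "dt_s"), smoothed = TRUE, t0 = t0_of(ts)
  )
}

#' First difference of a smoothed temperature series
#'
#' `d[i] = T[i+1] - T[i]`, in degC per (downsampled) sample. Device removal
#' produces a prominent negative excursion, reattachment a positive one;
#' ambient fluctuations stay small.
#'
#' @param ts A smoothed `wear_temp` tibble.
#' @return A tibble of class `wear_deriv` with columns `time_s` (midpoint
#'   between the two samples), `dtemp_c`, and attributes `dt_s`, `n_samples`.
#' @export
temp_derivative <- function(ts) {
  if (nrow(ts) < 2L) stop_data("temperature series too short to difference")
  if (!isTRUE(attr(ts, "smoothed"))) {
    warn("differencing an unsmoothed temperature series")
  }
  d <- diff(ts$temp_c)
  out <- tibble(
    time_s = (ts$time_s[-nrow(ts)] + ts$time_s[-1L]) / 2,
    dtemp_c = d
  )
  structure(out,
    dt_s = attr(ts, "dt_s"), n_samples = nrow(ts), t0 = t0_of(ts),
    class = c("wear_deriv", class(out))
  )
}

#' Standard temperature preprocessing pipeline
#'
#' Convenience composition: extract channel, decimate, smooth.
#'
#' @inheritParams temp_series
#' @inheritParams downsample_temp
#' @inheritParams smooth_temp
#' @return A smoothed, downsampled `wear_temp` tibble.
#' @export
preprocess_temp <- function(rec, factor = 6, window_samples = 11,
                            polyorder = 3) {
  rec |>
    temp_series() |>
    downsample_temp(factor) |>
    smooth_temp(window_samples, polyorder)
}
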