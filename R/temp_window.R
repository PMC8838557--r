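# Window-based temperature detectors: the absolute-threshold baselines the
# event-based method is compared against. Both scan the temperature series
# in fixed windows and call a window non-wear when its mean falls below a
# threshold; they differ only in how the threshold is set.

#' Fixed absolute temperature threshold
#'
#' @param base_c Threshold in degC (default 18).
#' @return A `wear_threshold` object with `resolved_c = base_c`.
#' @export
fixed_threshold <- function(base_c = 18) {
  structure(
    list(base_c = base_c, mode = "fixed", resolved_c = base_c,
         fallback = FALSE),
    class = "wear_threshold"
  )
}

#' Adaptive (midpoint) temperature threshold
#'
#' Splits the recording's temperature samples at `base_c`, averages the two
#' sides, and places the resolved threshold midway between the two means:
#' `resolved_c = (mean(T[T > base_c]) + mean(T[T < base_c])) / 2`. Samples
#' exactly equal to `base_c` join neither mean. If one side is empty (the
#' whole recording sits above or below `base_c`) the threshold falls back to
#' `base_c` with a warning flag. Because the split point is still the
#' absolute `base_c`, the adaptation inherits that anchor's climate
#' dependence: with a skin/ambient distribution far from `base_c` the
#' midpoint can land away from the true separating valley.
#'
#' @param ts A `wear_temp` tibble.
#' @param base_c Anchor temperature in degC (default 18).
#' @return A `wear_threshold` object (`base_c`, `mode`, `resolved_c`,
#'   `fallback`).
#' @export
adaptive_threshold <- function(ts, base_c = 18) {
  if (!nrow(ts)) stop_data("temperature series is empty")
  x <- ts$temp_c
  hi <- x[x > base_c]
  lo <- x[x < base_c]
  if (length(hi) && length(lo)) {
    resolved <- (mean(hi) + mean(lo)) / 2
    fallback <- FALSE
  } else {
    warn(sprintf(
      "all temperatures on one side of %g degC; threshold left at base",
      base_c
    ))
    resolved <- base_c
    fallback <- TRUE
  }
  structure(
    list(base_c = base_c, mode = "adaptive", resolved_c = resolved,
         fallback = fallback),
    class = "wear_threshold"
  )
}

#' Window-based temperature non-wear detection
#'
#' The series is scanned in non-overlapping windows (default 1 min); a window
#' whose mean temperature is strictly below the resolved threshold is
#' classified non-wear ("if lower": a mean exactly at the threshold stays
#' wear). No minimum-duration grouping is applied.
#'
#' @param ts A `wear_temp` tibble.
#' @param spec A `wear_threshold` from [fixed_threshold()] or
#'   [adaptive_threshold()].
#' @param window_s Window length in seconds (default 60).
#' @return A `wear_epochs` tibble.
#' @export
detect_window <- function(ts, spec = fixed_threshold(), window_s = 60) {
  stopifnot(inherits(spec, "wear_threshold"))
  dt <- attr(ts, "dt_s")
  m <- round(window_s / dt)
  if (m < 1) stop_config("window_s shorter than one temperature sample")
  k <- floor(nrow(ts) / m)
  means <- if (k > 0L) {
    colMeans(matrix(ts$temp_c[seq_len(k * m)], nrow = m))
  } else {
    numeric(0)
  }
  new_epoch_labels(as.integer(means < spec$resolved_c),
    epoch_s = window_s, t0 = t0_of(ts)
  )
}

#' @export
print.wear_threshold <- function(x, ...) {
  cat(sprintf(
    "<wear_threshold> mode=%s base=%g degC resolved=%g degC%s\n",
    x$mode, x$base_c, x$resolved_c,
    if (x$fallback) " (fallback: one-sided data)" else ""
  ))
  invisible(x)
}
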