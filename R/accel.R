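# Accelerometer-only non-wear detection: threshold on the per-minute
# standard deviation of the dynamic vector magnitude, with a minimum
# non-wear duration to suppress motion-artifact misclassification.

#' Accelerometer-based non-wear detection
#'
#' An epoch is provisionally non-wear when its vector-magnitude standard
#' deviation falls strictly below `thr_g` (13 mg by default, covering the
#' electrical noise floor of the sensor; a tie at exactly `thr_g` counts as
#' wear). Maximal runs of provisional non-wear shorter than `min_nonwear_s`
#' are then relabelled wear, including runs touching the recording
#' boundaries. The duration rule is what separates true non-wear from brief
#' stillness, but it also makes the method blind to removals shorter than
#' `min_nonwear_s`.
#'
#' @param sd A `wear_vmstd` tibble from [windowed_std()].
#' @param thr_g Threshold on the SD in g (default 0.013).
#' @param min_nonwear_s Minimum non-wear duration in seconds (default 1800).
#' @return A `wear_epochs` tibble (0 = wear, 1 = non-wear).
#' @export
detect_accel <- function(sd, thr_g = 0.013, min_nonwear_s = 1800) {
  if (!is_number(thr_g) || thr_g <= 0) stop_config("thr_g must be > 0")
  if (!is_number(min_nonwear_s) || min_nonwear_s < 0) {
    stop_config("min_nonwear_s must be >= 0")
  }
  epoch_s <- attr(sd, "window_s")
  labels <- as.integer(sd$sd_g < thr_g)
  if (length(labels) && min_nonwear_s > 0) {
    r <- rle(labels)
    short <- r$values == 1L & r$lengths * epoch_s < min_nonwear_s
    r$values[short] <- 0L
    labels <- inverse.rle(r)
  }
  new_epoch_labels(labels, epoch_s = epoch_s, t0 = t0_of(sd))
}
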