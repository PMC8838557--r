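# Combined accelerometer + temperature classification.

#' AND-combination of two epoch label vectors
#'
#' An epoch is non-wear only when both inputs call it non-wear, i.e. the
#' low-movement and low/changed-temperature conditions hold simultaneously.
#' The combination can only shrink the non-wear set, so false non-wear calls
#' unique to one sensor are suppressed, at the cost of inheriting each
#' sensor's misses.
#'
#' @param acc_e,temp_e `wear_epochs` tibbles on the same grid (equal
#'   `epoch_s`, `t0` and length).
#' @return A `wear_epochs` tibble; masks are OR-combined.
#' @export
combine_and <- function(acc_e, temp_e) {
  if (!identical(epoch_s_of(acc_e), epoch_s_of(temp_e)) ||
      !isTRUE(all.equal(t0_of(acc_e), t0_of(temp_e))) ||
      nrow(acc_e) != nrow(temp_e)) {
    stop_data("epoch grids do not align (epoch_s, t0 and length must match)")
  }
  new_epoch_labels(
    labels = as.integer(acc_e$label == 1L & temp_e$label == 1L),
    epoch_s = epoch_s_of(acc_e), t0 = t0_of(acc_e),
    mask = acc_e$mask | temp_e$mask
  )
}
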