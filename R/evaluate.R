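# Epoch-level validation metrics, positive = wear convention: sensitivity
# is the proportion of true wear epochs called wear, specificity the
# proportion of true non-wear epochs called non-wear, and NPV the proportion
# of predicted non-wear epochs that are truly non-wear.

#' Confusion-matrix metrics for one recording
#'
#' Counts epochs under positive = wear: TP = wear predicted wear, TN =
#' non-wear predicted non-wear, FP = non-wear predicted wear, FN = wear
#' predicted non-wear. Masked epochs (from either input or `mask`) are
#' excluded from all counts. A metric with a zero denominator is reported as
#' `NA`, never as 0.
#'
#' @param pred,truth `wear_epochs` tibbles on the same grid.
#' @param mask Optional extra logical mask of epochs to exclude.
#' @return A one-row tibble of class `wear_metrics` with columns `tp`, `fp`,
#'   `tn`, `fn`, `masked`, `n_epochs`, `sen`, `spe`, `acc`, `npv`.
#' @export
confusion <- function(pred, truth, mask = NULL) {
  if (!identical(epoch_s_of(pred), epoch_s_of(truth)) ||
      nrow(pred) != nrow(truth)) {
    stop_data("epoch grids do not align (epoch_s and length must match)")
  }
  excl <- pred$mask | truth$mask
  if (!is.null(mask)) excl <- excl | rep_len(as.logical(mask), nrow(pred))
  p <- pred$label[!excl]
  t <- truth$label[!excl]
  tp <- sum(p == 0L & t == 0L)
  fn <- sum(p == 1L & t == 0L)
  fp <- sum(p == 0L & t == 1L)
  tn <- sum(p == 1L & t == 1L)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    masked = sum(excl), n_epochs = nrow(pred),
    sen = ratio(tp, tp + fn),
    spe = ratio(tn, tn + fp),
    acc = ratio(tp + tn, tp + tn + fp + fn),
    npv = ratio(tn, tn + fn)
  )
  structure(out, class = c("wear_metrics", class(out)))
}

#' @describeIn confusion Long-format metric table.
#' @param x A `wear_metrics` row.
#' @param ... Unused.
#' @export
tidy.wear_metrics <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[c("sen", "spe", "acc", "npv")],
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}

#' @describeIn confusion The one-row metric tibble.
#' @export
glance.wear_metrics <- function(x, ...) as_tibble(x)

#' Aggregate per-recording metrics
#'
#' Unweighted mean and sample standard deviation of each metric over
#' recordings, skipping absent (`NA`) values per metric. With a single
#' usable value the SD is absent.
#'
#' @param reports A list of `wear_metrics` rows, or a tibble of them.
#' @return A tibble with columns `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(reports) {
  tab <- if (inherits(reports, "data.frame")) {
    as_tibble(reports)
  } else {
    bind_rows(lapply(reports, as_tibble))
  }
  if (!nrow(tab)) stop_data("no metric reports to aggregate")
  long <- tidyr::pivot_longer(
    tab[c("sen", "spe", "acc", "npv")],
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
  long |>
    group_by(.data$metric) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1L) {
        sd(.data$value, na.rm = TRUE)
      } else {
        NA_real_
      },
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    mutate(metric = factor(.data$metric, c("sen", "spe", "acc", "npv"))) |>
    arrange(.data$metric) |>
    mutate(metric = as.character(.data$metric))
}
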