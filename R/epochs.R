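# Epoch-level wear/non-wear labels and interval <-> epoch conversion.
#
# All algorithms are scored on a common grid of fixed-length epochs (default
# 1 min) carrying a binary label: 0 = wear, 1 = non-wear. Ground truth and
# algorithm output are both reduced to this representation so that detectors
# operating on different native resolutions stay comparable. Intervals are
# half-open [start_s, end_s) in seconds from the recording start.

#' Construct an epoch label table
#'
#' @param labels Integer vector of 0 (wear) / 1 (non-wear) labels.
#' @param epoch_s Epoch length in seconds.
#' @param t0 Time origin in seconds.
#' @param mask Logical vector marking epochs excluded from scoring (e.g.
#'   pocket-carriage epochs under `pocket_as = "exclude"`). Recycled.
#' @return A tibble of class `wear_epochs` with columns `epoch`, `time_s`
#'   (epoch start), `label`, `mask`, and attributes `epoch_s`, `t0`.
#' @export
new_epoch_labels <- function(labels, epoch_s = 60, t0 = 0, mask = FALSE) {
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L))) {
    stop_data("epoch labels must be 0 (wear) or 1 (non-wear)")
  }
  out <- tibble(
    epoch = seq_along(labels) - 1L,
    time_s = t0 + (seq_along(labels) - 1L) * epoch_s,
    label = labels,
    mask = rep_len(as.logical(mask), length(labels))
  )
  structure(out,
    epoch_s = epoch_s, t0 = t0,
    class = c("wear_epochs", class(out))
  )
}

epoch_s_of <- function(e) attr(e, "epoch_s")
t0_of <- function(e) attr(e, "t0") %||% 0

validate_intervals <- function(intervals,
                               labels = c("wear", "nonwear", "pocket")) {
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(intervals))) {
    stop_data(paste(
      "interval table must have columns",
      paste(need, collapse = ", ")
    ))
  }
  intervals <- as_tibble(intervals)[need]
  if (nrow(intervals)) {
    if (any(!intervals$label %in% labels)) {
      stop_data(paste("interval labels must be one of:",
                      paste(labels, collapse = ", ")))
    }
    if (any(intervals$start_s >= intervals$end_s)) {
      stop_data("intervals must satisfy start_s < end_s")
    }
    intervals <- arrange(intervals, .data$start_s)
    if (nrow(intervals) > 1L &&
        any(intervals$start_s[-1L] < intervals$end_s[-nrow(intervals)])) {
      stop_data("intervals must be non-overlapping")
    }
  }
  intervals
}

#' Convert labelled intervals to epoch labels
#'
#' An epoch is labelled non-wear when more than 50% of its span is covered by
#' non-wear intervals (a majority rule; exactly 50% stays wear). Gaps between
#' intervals default to wear. Pocket-carriage intervals are remapped according
#' to `pocket_as`: counted as wear (the device is near the body and every
#' algorithm treats it as worn), counted as non-wear, or excluded from scoring
#' via the `mask` column.
#'
#' @param intervals Tibble with columns `start_s`, `end_s`, `label`
#'   (`wear`/`nonwear`/`pocket`), half-open, non-overlapping, sorted.
#' @param duration_s Recording duration in seconds; a trailing partial epoch
#'   is dropped. Intervals reaching beyond it are clipped with a warning.
#' @param epoch_s Epoch length in seconds.
#' @param pocket_as How to score pocket intervals: `"wear"` (default),
#'   `"nonwear"`, or `"exclude"`.
#' @param t0 Time origin carried through to the output.
#' @return A `wear_epochs` tibble (see [new_epoch_labels()]).
#' @export
intervals_to_epochs <- function(intervals, duration_s, epoch_s = 60,
                                pocket_as = c("wear", "nonwear", "exclude"),
                                t0 = 0) {
  pocket_as <- match.arg(pocket_as)
  intervals <- validate_intervals(intervals)
  n <- floor(duration_s / epoch_s)
  if (n < 1L) stop_data("duration_s shorter than one epoch")

  if (nrow(intervals) && any(intervals$end_s > duration_s)) {
    warn("interval(s) beyond duration_s clipped")
    intervals$end_s <- pmin(intervals$end_s, duration_s)
    intervals <- intervals[intervals$start_s < intervals$end_s, ]
  }

  coverage <- numeric(n)
  pocket_hit <- logical(n)
  add_coverage <- function(start, end) {
    e0 <- max(0L, floor(start / epoch_s))
    e1 <- min(n - 1L, ceiling(end / epoch_s) - 1L)
    if (e1 < e0) return(NULL)
    idx <- e0:e1
    ov <- pmin(end, (idx + 1) * epoch_s) - pmax(start, idx * epoch_s)
    coverage[idx + 1L] <<- coverage[idx + 1L] + ov
    idx
  }
  for (i in seq_len(nrow(intervals))) {
    lab <- intervals$label[i]
    if (lab == "nonwear" || (lab == "pocket" && pocket_as == "nonwear")) {
      add_coverage(intervals$start_s[i], intervals$end_s[i])
    } else if (lab == "pocket" && pocket_as == "exclude") {
      e0 <- max(0L, floor(intervals$start_s[i] / epoch_s))
      e1 <- min(n - 1L, ceiling(intervals$end_s[i] / epoch_s) - 1L)
      if (e1 >= e0) pocket_hit[(e0:e1) + 1L] <- TRUE
    }
  }
  new_epoch_labels(
    labels = as.integer(coverage > epoch_s / 2),
    epoch_s = epoch_s, t0 = t0, mask = pocket_hit
  )
}

#' Convert epoch labels to non-wear intervals
#'
#' Maximal runs of non-wear epochs become half-open intervals; wear runs are
#' left implicit. Inverse of [intervals_to_epochs()] for interval sets aligned
#' to epoch boundaries.
#'
#' @param epochs A `wear_epochs` tibble.
#' @return A tibble with columns `start_s`, `end_s`, `label` (`"nonwear"`).
#' @export
epochs_to_intervals <- function(epochs) {
  epoch_s <- epoch_s_of(epochs)
  t0 <- t0_of(epochs)
  r <- rle(epochs$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  tibble(
    start_s = t0 + starts[keep] * epoch_s,
    end_s = t0 + ends[keep] * epoch_s,
    label = rep("nonwear", sum(keep))
  )
}

#' @export
print.wear_epochs <- function(x, ...) {
  cat(sprintf(
    "<wear_epochs> %d epochs of %gs, %d non-wear (%.1f%%), %d masked\n",
    nrow(x), epoch_s_of(x), sum(x$label == 1L),
    if (nrow(x)) 100 * mean(x$label == 1L) else 0, sum(x$mask)
  ))
  NextMethod()
}
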