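# Event-based temperature non-wear detection.
#
# Device removal and reattachment appear as prominent negative/positive
# excursions in the derivative of the smoothed temperature signal. The
# detector (1) collects all candidate peaks above a deliberately low
# derivative threshold, (2) classifies each candidate by the change in
# temperature *level* around it, retaining only candidates with a relative
# change of at least 3 degC, and (3) prunes retained events that violate
# removal -> reattachment alternation or whose interval temperature does not
# remain low. Because retention uses a relative temperature change rather
# than an absolute cut-off, the method transfers across climates, seasons
# and devices.

#' Parameters of the event-based detector
#'
#' @param deriv_thr_c Candidate-detection threshold on the temperature
#'   derivative, degC per (downsampled) sample. Deliberately low (0.02): it
#'   only has to catch every plausible transition, the retention stage does
#'   the discrimination.
#' @param retain_thr_c Relative temperature-level change (degC) required to
#'   retain a candidate as a removal/reattachment event; the comparison is
#'   `>=`, so a change of exactly `retain_thr_c` is retained.
#' @param bimoving_window_s Length of the two bi-directional moving-average
#'   windows W1/W2 (s); long enough to average out small fluctuations, short
#'   enough to track the trend.
#' @param steady_skip_s Option c: time skipped next to the candidate to let
#'   the sensor reach a steady state (s).
#' @param option_c_span_s Option c: total look-back/look-ahead span (s).
#' @return A list of class `wear_event_params`.
#' @export
event_params <- function(deriv_thr_c = 0.02, retain_thr_c = 3,
                         bimoving_window_s = 300, steady_skip_s = 600,
                         option_c_span_s = 3600) {
  vals <- list(
    deriv_thr_c = deriv_thr_c, retain_thr_c = retain_thr_c,
    bimoving_window_s = bimoving_window_s, steady_skip_s = steady_skip_s,
    option_c_span_s = option_c_span_s
  )
  if (!all(vapply(vals, is_number, logical(1))) || any(unlist(vals) <= 0)) {
    stop_config("all event parameters must be positive numbers")
  }
  structure(vals, class = "wear_event_params")
}

#' Detect candidate peaks in the temperature derivative
#'
#' A candidate is the largest-magnitude sample of each maximal run of
#' consecutive same-sign derivative samples with `|d| >= deriv_thr_c`.
#' Negative candidates are removal-like (temperature starts falling),
#' positive ones reattachment-like.
#'
#' @param d A `wear_deriv` tibble from [temp_derivative()].
#' @param deriv_thr_c Detection threshold in degC per sample.
#' @return A tibble of class `wear_candidates` with columns `cand`, `index`
#'   (anchor sample in the temperature series: the derivative at `index` is
#'   `T[index + 1] - T[index]`), `time_s`, `sign`, `amplitude`; sorted by
#'   time. Empty when the series is quiet.
#' @export
detect_candidates <- function(d, deriv_thr_c = 0.02) {
  v <- d$dtemp_c
  supra <- which(abs(v) >= deriv_thr_c)
  if (!length(supra)) {
    cands <- tibble(
      cand = integer(), index = integer(), time_s = numeric(),
      sign = integer(), amplitude = numeric()
    )
  } else {
    s <- sign(v[supra])
    new_run <- c(TRUE, diff(supra) > 1L | s[-1L] != s[-length(s)])
    grp <- cumsum(new_run)
    pick <- vapply(
      split(supra, grp),
      function(ii) ii[which.max(abs(v[ii]))],
      integer(1)
    )
    pick <- sort(unname(pick))
    cands <- tibble(
      cand = seq_along(pick),
      index = pick,
      time_s = d$time_s[pick],
      sign = as.integer(sign(v[pick])),
      amplitude = v[pick]
    )
  }
  structure(cands,
    dt_s = attr(d, "dt_s"), n_samples = attr(d, "n_samples"),
    t0 = t0_of(d),
    class = c("wear_candidates", class(cands))
  )
}

# Segment boundaries around candidate i: the previous / next candidate's
# anchor index, with virtual candidates at the series ends.
segment_bounds <- function(cands, i, n) {
  list(
    prev = if (i > 1L) cands$index[i - 1L] else 0L,
    idx = cands$index[i],
    nxt = if (i < nrow(cands)) cands$index[i + 1L] else n
  )
}

classify_row <- function(cands, i, mean_before, mean_after, reliable,
                         retain_thr_c, option) {
  t_diff <- abs(mean_before - mean_after)
  tibble(
    cand = cands$cand[i], index = cands$index[i],
    time_s = cands$time_s[i], sign = cands$sign[i],
    amplitude = cands$amplitude[i],
    mean_before = mean_before, mean_after = mean_after,
    t_diff = t_diff,
    reliable = reliable,
    retained = reliable && is.finite(t_diff) && t_diff >= retain_thr_c,
    option = option
  )
}

#' Classify a candidate peak by the surrounding temperature change
#'
#' The four options differ only in which samples are averaged on each side
#' of the candidate `c`:
#' * **a** — the entire segment back to the previous candidate and forward
#'   to the next one (virtual candidates at the series ends);
#' * **b** — the central half of each of those segments (segments shorter
#'   than 4 samples fall back to the full segment);
#' * **c** — fixed windows 60 min before/after the candidate, skipping the
#'   10 min adjacent to it so the sensor can reach a steady state, clipped
#'   to the series bounds and to the neighbouring candidates; a window left
#'   without samples makes the classification unreliable and the candidate
#'   is not retained, so this option abstains when candidates are packed
#'   closer than the skip;
#' * **d** — the mean of a 5-min window at the nearest local extremum of the
#'   temperature trend on each side, located with the bi-moving-window walk
#'   of [bimoving_extremum()] (a local maximum behind a removal, a local
#'   minimum ahead of it; roles swap for reattachment).
#'
#' A candidate is retained when `t_diff = |mean_before - mean_after|` is at
#' least `params$retain_thr_c`.
#'
#' @param ts The smoothed `wear_temp` series.
#' @param cands A `wear_candidates` tibble.
#' @param i Candidate row index to classify.
#' @param params A [event_params()] list.
#' @return A one-row tibble: candidate fields plus `mean_before`,
#'   `mean_after`, `t_diff`, `reliable`, `retained`, `option`.
#' @name classify_options
NULL

#' @rdname classify_options
#' @export
classify_option_a <- function(ts, cands, i, params = event_params()) {
  cs <- c(0, cumsum(ts$temp_c))
  classify_a_core(ts, cs, cands, i, params)
}

classify_a_core <- function(ts, cs, cands, i, params) {
  sb <- segment_bounds(cands, i, nrow(ts))
  mb <- cumsum_mean(cs, sb$prev + 1L, sb$idx)
  ma <- cumsum_mean(cs, sb$idx + 1L, sb$nxt)
  classify_row(cands, i, mb, ma, TRUE, params$retain_thr_c, "a")
}

#' @rdname classify_options
#' @export
classify_option_b <- function(ts, cands, i, params = event_params()) {
  cs <- c(0, cumsum(ts$temp_c))
  classify_b_core(ts, cs, cands, i, params)
}

central_half <- function(a, b) {
  len <- b - a + 1L
  if (len >= 4L) {
    q <- len %/% 4L
    c(a + q, b - q)
  } else {
    c(a, b)
  }
}

classify_b_core <- function(ts, cs, cands, i, params) {
  sb <- segment_bounds(cands, i, nrow(ts))
  rb <- central_half(sb$prev + 1L, sb$idx)
  ra <- central_half(sb$idx + 1L, sb$nxt)
  mb <- cumsum_mean(cs, rb[1L], rb[2L])
  ma <- cumsum_mean(cs, ra[1L], ra[2L])
  classify_row(cands, i, mb, ma, TRUE, params$retain_thr_c, "b")
}

#' @rdname classify_options
#' @export
classify_option_c <- function(ts, cands, i, params = event_params()) {
  cs <- c(0, cumsum(ts$temp_c))
  m <- classify_c_core(ts, cs, cands, i, params)
  classify_row(cands, i, m$mean_before, m$mean_after, m$reliable,
               params$retain_thr_c, "c")
}

classify_c_core <- function(ts, cs, cands, i, params) {
  t_c <- cands$time_s[i]
  tt <- ts$time_s
  n <- nrow(ts)
  span <- params$option_c_span_s
  skip <- params$steady_skip_s
  prev_t <- if (i > 1L) cands$time_s[i - 1L] else -Inf
  nxt_t <- if (i < nrow(cands)) cands$time_s[i + 1L] else Inf
  lo_b <- max(t_c - span, prev_t)
  hi_b <- t_c - skip
  lo_a <- t_c + skip
  hi_a <- min(t_c + span, nxt_t)
  eps <- 1e-9
  b1 <- findInterval(lo_b - eps, tt) + 1L
  b2 <- findInterval(hi_b + eps, tt)
  a1 <- findInterval(lo_a - eps, tt) + 1L
  a2 <- findInterval(hi_a + eps, tt)
  b2 <- min(b2, n); a2 <- min(a2, n)
  list(
    mean_before = if (b1 <= b2) cumsum_mean(cs, b1, b2) else NA_real_,
    mean_after = if (a1 <= a2) cumsum_mean(cs, a1, a2) else NA_real_,
    reliable = b1 <= b2 && a1 <= a2
  )
}

#' Locate the nearest local extremum of the temperature trend
#'
#' Two adjacent moving-average windows, W1 (nearer the anchor) and W2
#' (further away in the travel direction), are walked away from `t_anchor`
#' in steps of one window length. While the mean over W1 stays on the
#' approach side of the mean over W2 (below it when seeking a maximum, above
#' it when seeking a minimum) the trend still rises/falls away from the
#' anchor, so W1 takes W2's place and W2 shifts one window further. When the
#' comparison first fails, a local extremum of the trend has been passed and
#' the current W1 mean is returned as the temperature level there.
#'
#' @param ts A `wear_temp` tibble.
#' @param t_anchor Anchor time in seconds (e.g. a candidate peak time).
#' @param direction `"backward"` (before the anchor) or `"forward"`.
#' @param window_s Window length in seconds (default 300).
#' @param mode Seek a local `"max"` or `"min"` of the trend.
#' @return A list with `t_extremum` (centre of the final W1, s), `mean_w1`
#'   (degC) and `flagged` (`TRUE` when fewer than two windows fitted between
#'   the anchor and the series end).
#' @export
bimoving_extremum <- function(ts, t_anchor,
                              direction = c("backward", "forward"),
                              window_s = 300, mode = c("max", "min")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  cs <- c(0, cumsum(ts$temp_c))
  anchor <- findInterval(t_anchor, ts$time_s)
  bimoving_core(ts, cs, anchor, direction, window_s, mode)
}

bimoving_core <- function(ts, cs, anchor, direction, window_s, mode) {
  n <- nrow(ts)
  dt <- attr(ts, "dt_s")
  w <- max(1L, as.integer(round(window_s / dt)))
  if (direction == "backward") {
    b1 <- max(1L, min(anchor, n))
    a1 <- max(1L, b1 - w + 1L)
  } else {
    a1 <- min(n, max(anchor + 1L, 1L))
    b1 <- min(n, a1 + w - 1L)
  }
  m1 <- cumsum_mean(cs, a1, b1)
  next_win <- function(a, b) {
    if (direction == "backward") {
      if (a <= 1L) return(NULL)
      c(max(1L, a - w), a - 1L)
    } else {
      if (b >= n) return(NULL)
      c(b + 1L, min(n, b + w))
    }
  }
  w2 <- next_win(a1, b1)
  if (is.null(w2)) {
    return(list(
      t_extremum = mean(ts$time_s[c(a1, b1)]), mean_w1 = m1, flagged = TRUE
    ))
  }
  repeat {
    m2 <- cumsum_mean(cs, w2[1L], w2[2L])
    towards <- if (mode == "max") m1 < m2 else m1 > m2
    if (!towards) break
    a1 <- w2[1L]; b1 <- w2[2L]; m1 <- m2
    w2 <- next_win(a1, b1)
    if (is.null(w2)) break  # extremum at the series boundary
  }
  list(
    t_extremum = mean(ts$time_s[c(a1, b1)]), mean_w1 = m1, flagged = FALSE
  )
}

#' @rdname classify_options
#' @export
classify_option_d <- function(ts, cands, i, params = event_params()) {
  cs <- c(0, cumsum(ts$temp_c))
  m <- classify_d_core(ts, cs, cands, i, params)
  classify_row(cands, i, m$mean_before, m$mean_after, m$reliable,
               params$retain_thr_c, "d")
}

classify_d_core <- function(ts, cs, cands, i, params) {
  idx <- cands$index[i]
  removal <- cands$sign[i] < 0
  bef <- bimoving_core(
    ts, cs, idx, "backward", params$bimoving_window_s,
    if (removal) "max" else "min"
  )
  aft <- bimoving_core(
    ts, cs, idx, "forward", params$bimoving_window_s,
    if (removal) "min" else "max"
  )
  list(
    mean_before = bef$mean_w1, mean_after = aft$mean_w1,
    reliable = !(bef$flagged && aft$flagged)
  )
}

classify_candidates <- function(ts, cands, option, params) {
  core <- switch(option,
    a = classify_a_core, b = classify_b_core,
    c = classify_c_core, d = classify_d_core,
    stop_config(sprintf("unknown classification option '%s'", option))
  )
  k <- nrow(cands)
  if (!k) {
    return(tibble(
      cand = integer(), index = integer(), time_s = numeric(),
      sign = integer(), amplitude = numeric(), mean_before = numeric(),
      mean_after = numeric(), t_diff = numeric(), reliable = logical(),
      retained = logical(), option = character()
    ))
  }
  cs <- c(0, cumsum(ts$temp_c))
  n <- nrow(ts)
  idx <- cands$index
  prev <- c(0L, idx[-k])
  nxt <- c(idx[-1L], n)
  if (option == "a") {
    mb <- (cs[idx + 1L] - cs[prev + 1L]) / (idx - prev)
    ma <- (cs[nxt + 1L] - cs[idx + 1L]) / (nxt - idx)
    rel <- rep(TRUE, k)
  } else if (option == "b") {
    cb <- t(vapply(seq_len(k),
                   function(i) central_half(prev[i] + 1L, idx[i]),
                   integer(2)))
    ca <- t(vapply(seq_len(k),
                   function(i) central_half(idx[i] + 1L, nxt[i]),
                   integer(2)))
    mb <- (cs[cb[, 2L] + 1L] - cs[cb[, 1L]]) / (cb[, 2L] - cb[, 1L] + 1L)
    ma <- (cs[ca[, 2L] + 1L] - cs[ca[, 1L]]) / (ca[, 2L] - ca[, 1L] + 1L)
    rel <- rep(TRUE, k)
  } else {
    mb <- ma <- numeric(k)
    rel <- logical(k)
    for (i in seq_len(k)) {
      row <- core(ts, cs, cands, i, params)
      mb[i] <- row$mean_before
      ma[i] <- row$mean_after
      rel[i] <- row$reliable
    }
  }
  t_diff <- abs(mb - ma)
  tibble(
    cand = cands$cand, index = idx, time_s = cands$time_s,
    sign = cands$sign, amplitude = cands$amplitude,
    mean_before = mb, mean_after = ma, t_diff = t_diff,
    reliable = rel,
    retained = rel & is.finite(t_diff) & t_diff >= params$retain_thr_c,
    option = option
  )
}

# Second smoothing pass on the segments between candidates, removing small
# spurious fluctuations without blurring the transitions at the candidates
# themselves. Segments shorter than the filter window are left untouched.
resmooth_between <- function(ts, cands, window_samples = 11, polyorder = 3) {
  if (!nrow(cands)) return(ts)
  n <- nrow(ts)
  starts <- c(1L, cands$index + 1L)
  ends <- c(cands$index, n)
  x <- ts$temp_c
  for (j in seq_along(starts)) {
    if (ends[j] - starts[j] + 1L >= window_samples) {
      seg <- starts[j]:ends[j]
      x[seg] <- signal::sgolayfilt(x[seg], p = polyorder, n = window_samples)
    }
  }
  new_temp_series(ts$time_s, x,
    dt_s = attr(ts, "dt_s"), smoothed = TRUE, t0 = t0_of(ts)
  )
}

#' Prune retained events and emit non-wear intervals
#'
#' Enforces removal (-) -> reattachment (+) alternation and the requirement
#' that the temperature stays low while the device is off:
#' * consecutive same-sign retained events are repaired by keeping the one
#'   with the largest derivative magnitude (the strongest physical
#'   transition marker) and discarding the rest;
#' * each (-, +) pair becomes a candidate non-wear interval; an unmatched
#'   leading + opens an interval from the series start, an unmatched final -
#'   extends to the series end;
#' * an interval is discarded unless the temperature reaches the removal's
#'   after-level + `retain_thr_c` and, having reached it, never stays above
#'   that level for longer than one bi-moving window (the relaxation tails
#'   at the interval ends necessarily pass through the level; a mid-interval
#'   return to skin temperature does not);
#' * consecutive intervals separated by a supposed wear gap in which the
#'   temperature never rises back above that same level are merged: the
#'   intervening reattachment/removal pair was spurious, the device stayed
#'   off throughout.
#'
#' @param classified Retained classification rows (from
#'   [classify_options]), sorted by time.
#' @param ts The smoothed `wear_temp` series.
#' @param params A [event_params()] list.
#' @return A tibble of non-wear intervals (`start_s`, `end_s`, `label`),
#'   with the per-event audit (column `pruned_reason`) attached as attribute
#'   `"audit"`. Events pruned here leave their epochs labelled wear.
#' @export
prune_events <- function(classified, ts, params = event_params()) {
  ev <- arrange(as_tibble(classified), .data$time_s)
  ev$pruned_reason <- NA_character_
  empty <- tibble(start_s = numeric(), end_s = numeric(), label = character())
  if (!nrow(ev)) {
    return(structure(empty, audit = ev))
  }

  # alternation repair: one event per same-sign run, strongest peak wins
  run <- cumsum(c(TRUE, ev$sign[-1L] != ev$sign[-nrow(ev)]))
  keep <- unlist(lapply(split(seq_len(nrow(ev)), run), function(ii) {
    ii[which.max(abs(ev$amplitude[ii]))]
  }), use.names = FALSE)
  ev$pruned_reason[setdiff(seq_len(nrow(ev)), keep)] <- "alternation"

  dt <- attr(ts, "dt_s")
  t_start <- ts$time_s[1L]
  t_end <- ts$time_s[nrow(ts)] + dt

  low_check <- function(lo, hi, low_level) {
    idx <- which(ts$time_s > lo & ts$time_s < hi)
    if (!length(idx)) return("empty_interval")
    lowlim <- low_level + params$retain_thr_c
    below <- ts$temp_c[idx] <= lowlim
    first_low <- which(below)[1L]
    if (is.na(first_low)) return("never_low")
    rest <- below[first_low:length(below)]
    r <- rle(rest)
    high_runs <- r$lengths[!r$values]
    if (length(high_runs) &&
        max(high_runs) * dt > params$bimoving_window_s) {
      return("not_low")
    }
    NA_character_
  }

  kept_idx <- sort(keep)
  intervals <- list()
  open <- NULL  # row index of an open removal
  for (i in kept_idx) {
    if (ev$sign[i] < 0) {
      open <- i
    } else if (!is.null(open)) {
      intervals[[length(intervals) + 1L]] <-
        list(lo = ev$time_s[open], hi = ev$time_s[i],
             low = ev$mean_after[open], members = c(open, i))
      open <- NULL
    } else if (!length(intervals) && i == kept_idx[1L]) {
      # leading reattachment: the recording started with the device off
      intervals[[length(intervals) + 1L]] <-
        list(lo = t_start, hi = ev$time_s[i],
             low = ev$mean_before[i], members = i)
    } else {
      ev$pruned_reason[i] <- "alternation"
    }
  }
  if (!is.null(open)) {
    intervals[[length(intervals) + 1L]] <-
      list(lo = ev$time_s[open], hi = t_end,
           low = ev$mean_after[open], members = open)
  }

  surv <- list()
  for (iv in intervals) {
    reason <- low_check(iv$lo, iv$hi, iv$low)
    if (is.na(reason)) {
      surv[[length(surv) + 1L]] <- iv
    } else {
      ev$pruned_reason[iv$members] <- reason
    }
  }

  # Merge intervals separated by a supposed wear gap in which the
  # temperature never returns towards the skin level: the intervening
  # reattachment/removal pair was spurious (the device stayed off).
  i <- 1L
  while (i < length(surv)) {
    gap_idx <- which(ts$time_s > surv[[i]]$hi & ts$time_s < surv[[i + 1L]]$lo)
    gap_high <- if (length(gap_idx)) max(ts$temp_c[gap_idx]) else -Inf
    if (gap_high < surv[[i]]$low + params$retain_thr_c) {
      inner <- c(
        surv[[i]]$members[length(surv[[i]]$members)],
        surv[[i + 1L]]$members[1L]
      )
      ev$pruned_reason[inner] <- "gap_not_high"
      surv[[i]]$hi <- surv[[i + 1L]]$hi
      surv[[i]]$members <- c(
        surv[[i]]$members[1L],
        surv[[i + 1L]]$members[length(surv[[i + 1L]]$members)]
      )
      surv[[i + 1L]] <- NULL
    } else {
      i <- i + 1L
    }
  }

  out <- empty
  for (iv in surv) {
    out <- bind_rows(out, tibble(
      start_s = iv$lo, end_s = iv$hi, label = "nonwear"
    ))
  }
  structure(arrange(out, .data$start_s), audit = ev)
}

#' Event-based temperature non-wear detection
#'
#' Full pipeline: derivative -> candidate peaks -> a second smoothing pass
#' on the segments between candidates -> per-candidate classification
#' (options a-d) -> retention at the relative threshold -> pruning ->
#' non-wear intervals and epoch labels. Deterministic for fixed input and
#' parameters.
#'
#' @param ts A smoothed `wear_temp` series (see [preprocess_temp()]).
#' @param params A [event_params()] list.
#' @param option Classification option `"a"`, `"b"`, `"c"` or `"d"`
#'   (default; the bi-moving-window variant).
#' @param epoch_s Epoch length for the label grid (s).
#' @param duration_s Grid duration; defaults to the series span.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters for the
#'   between-candidate smoothing pass.
#' @return An object of class `wear_events`: list with `intervals`,
#'   `epochs`, `audit` (per-candidate table: time, sign, amplitude, means,
#'   `t_diff`, `retained`, `pruned_reason`), `candidates`, `params`,
#'   `option`. `tidy()` returns the audit table, `glance()` a one-row
#'   summary.
#' @export
detect_event <- function(ts, params = event_params(), option = "d",
                         epoch_s = 60, duration_s = NULL,
                         sg_window = 11, sg_polyorder = 3) {
  if (!isTRUE(attr(ts, "smoothed"))) {
    warn("running event detection on an unsmoothed temperature series")
  }
  d <- temp_derivative(ts)
  cands <- detect_candidates(d, params$deriv_thr_c)
  ts2 <- resmooth_between(ts, cands, sg_window, sg_polyorder)
  cls <- classify_candidates(ts2, cands, option, params)
  pruned <- prune_events(cls[cls$retained, , drop = FALSE], ts2, params)
  audit <- dplyr::left_join(
    cls,
    select(attr(pruned, "audit"), "cand", "pruned_reason"),
    by = "cand"
  )
  dt <- attr(ts, "dt_s")
  if (is.null(duration_s)) {
    duration_s <- ts$time_s[nrow(ts)] + dt - ts$time_s[1L]
  }
  epochs <- intervals_to_epochs(pruned, duration_s,
    epoch_s = epoch_s, t0 = t0_of(ts)
  )
  structure(
    list(
      intervals = as_tibble(pruned), epochs = epochs, audit = audit,
      candidates = cands, params = params, option = option
    ),
    class = "wear_events"
  )
}

#' @export
print.wear_events <- function(x, ...) {
  cat(sprintf(
    "<wear_events> option %s: %d candidates -> %d retained -> %d non-wear interval(s), %.1f min non-wear\n",
    x$option, nrow(x$audit), sum(x$audit$retained), nrow(x$intervals),
    sum(x$intervals$end_s - x$intervals$start_s) / 60
  ))
  invisible(x)
}

#' @describeIn detect_event Per-candidate audit table.
#' @param x A `wear_events` object.
#' @param ... Unused.
#' @export
tidy.wear_events <- function(x, ...) x$audit

#' @describeIn detect_event One-row summary of the detection run.
#' @export
glance.wear_events <- function(x, ...) {
  tibble(
    option = x$option,
    n_candidates = nrow(x$audit),
    n_retained = sum(x$audit$retained),
    n_events = nrow(x$intervals),
    nonwear_s = sum(x$intervals$end_s - x$intervals$start_s)
  )
}
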