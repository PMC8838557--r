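# Fixture builders and independent oracles shared across test files.
# Oracles are written as plain brute-force code, independent of the
# implementation paths they check.

`%||%` <- function(x, y) if (is.null(x)) y else x

# -- fixture builders --------------------------------------------------------

# Temperature series from raw values on a uniform grid.
make_ts <- function(values, dt_s = 6, smoothed = TRUE, t0 = 0) {
  wearcheck:::new_temp_series(
    time_s = (seq_along(values) - 1) * dt_s,
    temp_c = values, dt_s = dt_s, smoothed = smoothed, t0 = t0
  )
}

# Piecewise-exponential temperature profile: `levels` are the target values
# of consecutive segments, `breaks_s` their start times (first must be 0),
# tau the relaxation constant. Starts at the first level exactly.
make_exp_profile <- function(levels, breaks_s, duration_s, tau_s,
                             dt_s = 6, noise_sd = 0) {
  times <- seq(0, duration_s - dt_s, by = dt_s)
  x <- numeric(length(times))
  cur <- levels[1]
  for (k in seq_along(levels)) {
    lo <- breaks_s[k]
    hi <- if (k < length(levels)) breaks_s[k + 1] else duration_s
    idx <- which(times >= lo & times < hi)
    x[idx] <- levels[k] + (cur - levels[k]) * exp(-(times[idx] - lo) / tau_s)
    cur <- levels[k] + (cur - levels[k]) * exp(-(hi - lo) / tau_s)
  }
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  make_ts(x, dt_s = dt_s)
}

# Minimal recording around given axis vectors.
make_recording <- function(ax, ay, az, fs_acc = 100,
                           temp = NULL, fs_temp = 1) {
  n <- length(ax)
  if (is.null(temp)) {
    temp <- tibble::tibble(
      time_s = seq(0, by = 1 / fs_temp,
                   length.out = max(2, floor(n / fs_acc * fs_temp))),
      temp_c = 33
    )
  }
  wearcheck:::new_recording(
    acc = tibble::tibble(ax_g = ax, ay_g = ay, az_g = az),
    fs_acc = fs_acc, temp = temp, fs_temp = fs_temp,
    t0 = 0, duration_s = n / fs_acc
  )
}

# Hand-built candidate table for window-logic tests (bypasses detection).
make_cands <- function(index, sign, ts, amplitude = sign * 0.5) {
  tibble::tibble(
    cand = seq_along(index), index = as.integer(index),
    time_s = (ts$time_s[index] + ts$time_s[pmin(index + 1L, nrow(ts))]) / 2,
    sign = as.integer(sign), amplitude = amplitude
  )
}

# -- independent oracles -----------------------------------------------------

# Run-length oracle for the accelerometer duration rule: plain loop.
oracle_accel <- function(sd_vals, thr, min_epochs) {
  lab <- ifelse(sd_vals < thr, 1L, 0L)
  n <- length(lab)
  i <- 1L
  while (i <= n) {
    if (lab[i] == 1L) {
      j <- i
      while (j < n && lab[j + 1L] == 1L) j <- j + 1L
      if (j - i + 1L < min_epochs) lab[i:j] <- 0L
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  lab
}

# Brute-force excursion scan for candidate detection: walk the derivative,
# collect maximal same-sign supra-threshold runs, keep the largest |value|.
oracle_candidates <- function(v, thr) {
  out <- integer(0)
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (abs(v[i]) >= thr) {
      s <- sign(v[i])
      j <- i
      while (j < n && abs(v[j + 1L]) >= thr && sign(v[j + 1L]) == s) {
        j <- j + 1L
      }
      run <- i:j
      out <- c(out, run[which.max(abs(v[run]))])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Exhaustive bi-moving oracle: tile adjacent windows away from the anchor,
# scan the window-mean sequence for the first local extremum.
oracle_bimoving <- function(x, anchor, direction, w, mode) {
  n <- length(x)
  wins <- list()
  if (direction == "backward") {
    b <- anchor
    while (b >= 1L) {
      a <- max(1L, b - w + 1L)
      wins[[length(wins) + 1L]] <- c(a, b)
      if (a == 1L) break
      b <- a - 1L
    }
  } else {
    a <- anchor + 1L
    while (a <= n) {
      b <- min(n, a + w - 1L)
      wins[[length(wins) + 1L]] <- c(a, b)
      if (b == n) break
      a <- b + 1L
    }
  }
  means <- vapply(wins, function(wn) mean(x[wn[1L]:wn[2L]]), numeric(1))
  if (length(means) == 1L) return(means[1L])
  for (j in seq_len(length(means) - 1L)) {
    stopnow <- if (mode == "max") {
      means[j] >= means[j + 1L]
    } else {
      means[j] <= means[j + 1L]
    }
    if (stopnow) return(means[j])
  }
  means[length(means)]
}

# Run-length encoding oracle for epochs -> intervals.
oracle_intervals <- function(labels, epoch_s) {
  out <- NULL
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] == 1L) {
      j <- i
      while (j < n && labels[j + 1L] == 1L) j <- j + 1L
      out <- rbind(out, c((i - 1L) * epoch_s, j * epoch_s))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Short temperature-only simulation used by several files.
quick_temp_sim <- function(seed, duration_s = 86400, ...) {
  simulate_recording(
    sim_scenario(duration_s = duration_s, seed = seed, ...),
    channels = "temp"
  )
}
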