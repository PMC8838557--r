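# Ground-truthed simulator of multi-day wear protocols.
#
# Emulates the physical structure the detectors exploit: the device
# temperature relaxes first-order (Newton cooling) between skin temperature
# while worn (or carried in a pocket) and the storage environment while off;
# acceleration variance is high during active wear, low during sleep,
# sedentary wear and static non-wear. Each simulated day contains a short
# (< 1 h) removal plus a second task cycling over a long (> 1 h) removal,
# pocket carriage, and a removal followed by wrong-orientation reattachment,
# with nightly sleep blocks. All randomness derives from the scenario seed.

#' Define a simulation scenario
#'
#' Defaults describe a 3-day continuous recording with the device taped to
#' the lower back: skin-contact temperature around 33 degC, indoor ambient
#' 18-23 degC, outdoor ambient -3 to 17 degC, 100 Hz acceleration and 1 Hz
#' temperature sampling. Thermal time constants are chosen so that
#' attachment/detachment transients settle within about 10 minutes.
#'
#' @param duration_s Recording length in seconds (default 3 days).
#' @param fs_acc,fs_temp Sampling rates (Hz).
#' @param skin_c Skin-contact equilibrium temperature (degC).
#' @param ambient_day_c Indoor ambient range, degC (short removals are
#'   stored indoors).
#' @param ambient_out_c Outdoor/storage ambient range, degC (long and
#'   wrong-orientation removals).
#' @param tau_attach_s,tau_detach_s Thermal time constants for warming after
#'   attachment / cooling after removal (s).
#' @param schedule Optional explicit event table (`start_s`, `end_s`,
#'   `label` in `nonwear`/`pocket`, optional `task`, `ambient_c`); `NULL`
#'   generates the default daily protocol. Supply a zero-row tibble for a
#'   removal-free recording.
#' @param noise_sd_acc_g Accelerometer sensor noise SD (g) during static
#'   non-wear.
#' @param sensor_noise_sd_c Temperature sensor noise SD (degC).
#' @param seed Integer seed; the simulation is a pure function of the
#'   scenario including this seed.
#' @return A list of class `wear_scenario`.
#' @export
sim_scenario <- function(duration_s = 259200, fs_acc = 100, fs_temp = 1,
                         skin_c = 33,
                         ambient_day_c = c(18, 23),
                         ambient_out_c = c(-3, 17),
                         tau_attach_s = 300, tau_detach_s = 600,
                         schedule = NULL,
                         noise_sd_acc_g = 0.002,
                         sensor_noise_sd_c = 0.05,
                         seed = 1L) {
  stopifnot(
    is_number(duration_s), duration_s >= 60,
    is_number(fs_acc), fs_acc > 0, is_number(fs_temp), fs_temp > 0,
    is_number(skin_c), length(ambient_day_c) == 2L,
    length(ambient_out_c) == 2L,
    is_number(tau_attach_s), tau_attach_s > 0,
    is_number(tau_detach_s), tau_detach_s > 0,
    is_number(noise_sd_acc_g), noise_sd_acc_g >= 0,
    is_number(sensor_noise_sd_c), sensor_noise_sd_c >= 0,
    is_count(seed)
  )
  if (!is.null(schedule)) {
    schedule <- as_tibble(schedule)
    if (nrow(schedule)) {
      if (any(schedule$end_s > duration_s) || any(schedule$start_s < 0)) {
        stop_config("schedule events must lie within [0, duration_s]")
      }
      validate_intervals(schedule[c("start_s", "end_s", "label")],
        labels = c("nonwear", "pocket")
      )
      if (!"task" %in% names(schedule)) schedule$task <- "custom"
      if (!"ambient_c" %in% names(schedule)) {
        schedule$ambient_c <- mean(ambient_out_c)
      }
    } else {
      schedule <- empty_schedule()
    }
  }
  structure(
    list(
      duration_s = duration_s, fs_acc = fs_acc, fs_temp = fs_temp,
      skin_c = skin_c, ambient_day_c = ambient_day_c,
      ambient_out_c = ambient_out_c,
      tau_attach_s = tau_attach_s, tau_detach_s = tau_detach_s,
      schedule = schedule,
      noise_sd_acc_g = noise_sd_acc_g,
      sensor_noise_sd_c = sensor_noise_sd_c,
      seed = as.integer(seed)
    ),
    class = "wear_scenario"
  )
}

empty_schedule <- function() {
  tibble(
    start_s = numeric(), end_s = numeric(), label = character(),
    task = character(), ambient_c = numeric()
  )
}

runif1 <- function(lo, hi) runif(1L, lo, hi)

# Daily protocol: one short removal every day; a second task cycling over
# long removal, pocket carriage, wrong-orientation reattachment; nightly
# sleep of 7-9 h. Times are drawn within fixed windows so tasks and sleep
# can never collide. Day time origin is 08:00.
make_schedule <- function(sc) {
  days <- ceiling(sc$duration_s / 86400)
  ev <- list()
  sleep <- list()
  for (d in seq_len(days) - 1L) {
    base <- d * 86400
    s1 <- base + 3600 * runif1(1, 4)
    ev[[length(ev) + 1L]] <- tibble(
      start_s = s1, end_s = s1 + 60 * runif1(20, 50),
      label = "nonwear", task = "short_removal",
      ambient_c = runif1(sc$ambient_day_c[1L], sc$ambient_day_c[2L])
    )
    s2 <- base + 3600 * runif1(5, 8)
    cyc <- d %% 3L
    ev[[length(ev) + 1L]] <- if (cyc == 0L) {
      tibble(
        start_s = s2, end_s = s2 + 3600 * runif1(1.5, 3),
        label = "nonwear", task = "long_removal",
        ambient_c = runif1(sc$ambient_out_c[1L], sc$ambient_out_c[2L])
      )
    } else if (cyc == 1L) {
      tibble(
        start_s = s2, end_s = s2 + 60 * runif1(40, 90),
        label = "pocket", task = "pocket", ambient_c = NA_real_
      )
    } else {
      tibble(
        start_s = s2, end_s = s2 + 60 * runif1(20, 45),
        label = "nonwear", task = "wrong_orientation",
        ambient_c = runif1(sc$ambient_out_c[1L], sc$ambient_out_c[2L])
      )
    }
    sl <- base + 3600 * runif1(13.5, 15)
    sleep[[length(sleep) + 1L]] <- tibble(
      start_s = sl, end_s = sl + 3600 * runif1(7, 9)
    )
  }
  ev <- bind_rows(ev)
  sleep <- bind_rows(sleep)
  ev <- ev[ev$end_s <= sc$duration_s, ]
  sleep <- sleep[sleep$start_s < sc$duration_s, ]
  sleep$end_s <- pmin(sleep$end_s, sc$duration_s)
  list(events = arrange(ev, .data$start_s), sleep = sleep)
}

# Piecewise-exponential device temperature: target = skin while worn or in
# the pocket, target = event ambient while off; tau depends on direction.
make_temp <- function(sc, events) {
  n <- floor(sc$duration_s * sc$fs_temp)
  dt <- 1 / sc$fs_temp
  times <- (seq_len(n) - 1L) * dt
  temp <- numeric(n)
  nw <- events[events$label == "nonwear", , drop = FALSE]
  # breakpoints: alternating wear / non-wear segments
  seg_start <- 0
  t_cur <- sc$skin_c
  fill <- function(lo, hi, target, tau, t_in) {
    idx <- which(times >= lo & times < hi)
    if (length(idx)) {
      temp[idx] <<- target + (t_in - target) * exp(-(times[idx] - lo) / tau)
    }
    target + (t_in - target) * exp(-(hi - lo) / tau)
  }
  for (i in seq_len(nrow(nw))) {
    t_cur <- fill(seg_start, nw$start_s[i], sc$skin_c, sc$tau_attach_s, t_cur)
    t_cur <- fill(nw$start_s[i], nw$end_s[i], nw$ambient_c[i],
                  sc$tau_detach_s, t_cur)
    seg_start <- nw$end_s[i]
  }
  fill(seg_start, sc$duration_s, sc$skin_c, sc$tau_attach_s, t_cur)
  temp <- temp + rnorm(n, 0, sc$sensor_noise_sd_c)
  tibble(time_s = times, temp_c = temp)
}

# Per-minute behavioural states -> per-minute acceleration SD levels ->
# white noise per axis plus a piecewise-constant gravity vector.
make_acc <- function(sc, events, sleep) {
  n_min <- floor(sc$duration_s / 60)
  minute_mid <- (seq_len(n_min) - 0.5) * 60

  # daytime fabric: alternating active / sedentary bouts over the whole span
  state <- character(n_min)
  t <- 0L
  active <- TRUE
  while (t < n_min) {
    len <- if (active) round(runif1(2, 10)) else round(runif1(8, 25))
    len <- max(1L, min(len, n_min - t))
    state[(t + 1L):(t + len)] <- if (active) "active" else "sedentary"
    t <- t + len
    active <- !active
  }
  in_any <- function(tbl) {
    hit <- logical(n_min)
    for (i in seq_len(nrow(tbl))) {
      hit <- hit | (minute_mid > tbl$start_s[i] & minute_mid < tbl$end_s[i])
    }
    hit
  }
  state[in_any(sleep)] <- "sleep"
  # sparse posture shifts during sleep keep it distinguishable from a
  # perfectly static signal
  for (i in seq_len(nrow(sleep))) {
    t_shift <- sleep$start_s[i] + 60 * runif1(40, 100)
    while (t_shift < sleep$end_s[i] - 60) {
      state[max(1L, min(n_min, ceiling(t_shift / 60)))] <- "shift"
      t_shift <- t_shift + 60 * runif1(40, 100)
    }
  }
  state[in_any(events[events$label == "nonwear", ])] <- "nonwear"
  state[in_any(events[events$label == "pocket", ])] <- "pocket"
  # handling (clap protocol) in the wear minutes flanking each event,
  # including boundary minutes only partially covered by the event
  for (i in seq_len(nrow(events))) {
    cand <- c(
      floor(events$start_s[i] / 60), floor(events$start_s[i] / 60) + 1L,
      ceiling(events$end_s[i] / 60), ceiling(events$end_s[i] / 60) + 1L
    )
    cand <- cand[cand >= 1L & cand <= n_min]
    wearish <- state[cand] %in% c("active", "sedentary", "sleep")
    state[cand[wearish]] <- "handling"
  }

  lev <- numeric(n_min)
  draw <- function(s, lo, hi) {
    k <- sum(state == s)
    if (k) lev[state == s] <<- runif(k, lo, hi)
  }
  draw("active", 0.05, 0.3)
  draw("sedentary", 0.001, 0.008)
  draw("sleep", 0.001, 0.008)
  draw("shift", 0.05, 0.15)
  draw("handling", 0.05, 0.15)
  lev[state == "nonwear"] <- sc$noise_sd_acc_g
  k <- sum(state == "pocket")
  if (k) {
    lev[state == "pocket"] <- ifelse(runif(k) < 0.6,
      runif(k, 0.05, 0.3), runif(k, 0.001, 0.008)
    )
  }

  per_min <- as.integer(round(60 * sc$fs_acc))
  n_samp <- floor(sc$duration_s * sc$fs_acc)

  # gravity: (0,0,1) g, remapped after each wrong-orientation reattachment;
  # unit noise is scaled by the per-minute level and offset by gravity in
  # one compiled pass
  flips <- sort(events$end_s[events$task == "wrong_orientation"])
  seg_starts <- as.integer(c(1, floor(flips * sc$fs_acc) + 1))
  orient <- 1L + (seq_along(seg_starts) - 1L) %% 2L
  g <- rbind(c(0, 0, 1), c(1, 0, 0))
  axis_noise <- function(axis) {
    scale_noise_cpp(rnorm(n_samp), lev, per_min, g[orient, axis],
                    seg_starts)
  }
  acc <- tibble(
    ax_g = axis_noise(1L), ay_g = axis_noise(2L), az_g = axis_noise(3L)
  )
  list(acc = acc, state = state)
}

#' Simulate a recording with ground truth
#'
#' Pure function of the scenario (including its seed): repeated calls give
#' bit-identical output. The schedule, the temperature noise and the
#' acceleration noise are drawn from independently derived seeds, so the
#' temperature channel is identical whether or not the (much larger)
#' acceleration channel is generated.
#'
#' @param sc A [sim_scenario()].
#' @param channels `"full"` (both channels) or `"temp"` (temperature only;
#'   `recording$acc` is `NULL`).
#' @return A list of class `wear_simulation`: `recording`
#'   (`wear_recording`), `truth` (interval tibble with `nonwear` and
#'   `pocket` labels, exactly the schedule), `sleep` (sleep-block
#'   intervals), `schedule` (events with task and ambient metadata),
#'   `minute_state` (per-minute behavioural state driving the acceleration
#'   levels; `NULL` in temperature-only mode), and `scenario`.
#' @export
simulate_recording <- function(sc, channels = c("full", "temp")) {
  channels <- match.arg(channels)
  stopifnot(inherits(sc, "wear_scenario"))
  seeds <- withr::with_seed(sc$seed, sample.int(2147483646L, 3L))
  if (is.null(sc$schedule)) {
    sched <- withr::with_seed(seeds[1L], make_schedule(sc))
  } else {
    sched <- list(
      events = sc$schedule,
      sleep = tibble(start_s = numeric(), end_s = numeric())
    )
  }
  temp <- withr::with_seed(seeds[2L], make_temp(sc, sched$events))
  acc <- NULL
  minute_state <- NULL
  if (channels == "full") {
    gen <- withr::with_seed(
      seeds[3L], make_acc(sc, sched$events, sched$sleep)
    )
    acc <- gen$acc
    minute_state <- tibble(
      minute = seq_along(gen$state) - 1L,
      time_s = (seq_along(gen$state) - 1L) * 60,
      state = gen$state
    )
  }
  rec <- new_recording(
    acc = acc, fs_acc = sc$fs_acc,
    temp = temp, fs_temp = sc$fs_temp,
    t0 = 0, duration_s = sc$duration_s
  )
  structure(
    list(
      recording = rec,
      truth = sched$events[c("start_s", "end_s", "label")],
      sleep = sched$sleep,
      schedule = sched$events,
      minute_state = minute_state,
      scenario = sc
    ),
    class = "wear_simulation"
  )
}

#' Scenarios for a multi-participant protocol batch
#'
#' Derives `n` reproducible scenarios from one master seed, each with its
#' own randomized task times, ambient temperatures and sleep blocks.
#'
#' @param n Number of recordings.
#' @param seed Master seed.
#' @param ... Overrides passed to [sim_scenario()] (e.g. `duration_s`,
#'   `ambient_out_c`).
#' @return A list of `wear_scenario` objects.
#' @export
protocol_scenarios <- function(n, seed, ...) {
  stopifnot(is_count(n), is_count(seed))
  seeds <- withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
  purrr::map(seeds, function(s) sim_scenario(..., seed = s))
}

#' Simulate a protocol batch
#'
#' @inheritParams protocol_scenarios
#' @inheritParams simulate_recording
#' @return A list of `n` [simulate_recording()] results.
#' @export
protocol_batch <- function(n, seed, channels = "full", ...) {
  purrr::map(protocol_scenarios(n, seed, ...), simulate_recording,
             channels = channels)
}

#' @export
print.wear_scenario <- function(x, ...) {
  cat(sprintf(
    "<wear_scenario> %.1f days @ %g/%g Hz, skin %g degC, seed %d\n",
    x$duration_s / 86400, x$fs_acc, x$fs_temp, x$skin_c, x$seed
  ))
  invisible(x)
}
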