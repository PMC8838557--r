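# Event-based detector: candidate peaks, the four classification options,
# the bi-moving-window walk, pruning, and the assembled pipeline.

# classification row builder for pruning tests (bypasses detection)
make_classified <- function(ts, index, sign, amplitude,
                            mean_before, mean_after) {
  tibble::tibble(
    cand = seq_along(index), index = as.integer(index),
    time_s = ts$time_s[index], sign = as.integer(sign),
    amplitude = amplitude,
    mean_before = mean_before, mean_after = mean_after,
    t_diff = abs(mean_before - mean_after),
    reliable = TRUE, retained = TRUE, option = "d"
  )
}

step_series <- function(levels, lens, dt_s = 6) {
  make_ts(rep(levels, lens), dt_s = dt_s)
}

test_that("candidate detection matches a brute-force excursion scan", {
  # quiet series: nothing
  d <- temp_derivative(make_ts(rep(33, 500)))
  expect_equal(nrow(detect_candidates(d)), 0)

  # one smoothed 10 degC drop: exactly one removal-like candidate
  prof <- make_exp_profile(c(33, 23), c(0, 9000), 18000, tau_s = 600)
  d <- temp_derivative(prof)
  got <- detect_candidates(d)
  expect_equal(nrow(got), 1)
  expect_equal(got$sign, -1L)
  expect_equal(got$index, oracle_candidates(d$dtemp_c, 0.02))

  # drop then rise: two candidates in time order with signs (-1, +1)
  prof <- make_exp_profile(c(33, 23, 33), c(0, 9000, 14400), 27000,
                           tau_s = 600)
  d <- temp_derivative(prof)
  got <- detect_candidates(d)
  expect_equal(got$sign, c(-1L, 1L))
  expect_true(all(diff(got$time_s) > 0))
  expect_equal(got$index, oracle_candidates(d$dtemp_c, 0.02))

  # random wandering signals: oracle equivalence
  withr::with_seed(41, {
    for (rep in 1:15) {
      x <- 25 + cumsum(rnorm(400, 0, 0.02))
      d <- temp_derivative(make_ts(x))
      expect_equal(detect_candidates(d)$index,
                   oracle_candidates(d$dtemp_c, 0.02))
    }
  })
})

test_that("options a-d agree exactly on piecewise-constant signals", {
  ts <- step_series(c(33, 20), c(1200, 1200))  # 2 h + 2 h at dt = 6 s
  cands <- detect_candidates(temp_derivative(ts))
  expect_equal(nrow(cands), 1)
  rows <- lapply(
    list(classify_option_a, classify_option_b, classify_option_c,
         classify_option_d),
    function(f) f(ts, cands, 1)
  )
  for (r in rows) {
    expect_equal(r$t_diff, 13)
    expect_equal(r$mean_before, 33)
    expect_equal(r$mean_after, 20)
    expect_true(r$retained)
  }
})

test_that("a level change of exactly 3 degC is retained (>= semantics)", {
  ts <- step_series(c(30, 27), c(1200, 1200))
  cands <- detect_candidates(temp_derivative(ts))
  for (f in list(classify_option_a, classify_option_d)) {
    r <- f(ts, cands, 1)
    expect_equal(r$t_diff, 3)
    expect_true(r$retained)
  }
  # and just under the threshold is not
  ts2 <- step_series(c(30, 27.5), c(1200, 1200))
  cands2 <- detect_candidates(temp_derivative(ts2))
  expect_false(classify_option_d(ts2, cands2, 1)$retained)
})

test_that("symmetric fluctuations yield t_diff 0 and are dropped", {
  ts <- step_series(c(25, 25), c(100, 100))
  cands <- make_cands(100, -1, ts)
  expect_equal(classify_option_a(ts, cands, 1)$t_diff, 0)
  expect_false(classify_option_a(ts, cands, 1)$retained)
})

test_that("the first candidate's before-window starts at the series", {
  ts <- step_series(c(31, 22), c(400, 400))
  cands <- make_cands(400, -1, ts)
  r <- classify_option_a(ts, cands, 1)
  expect_equal(r$mean_before, mean(ts$temp_c[1:400]))
  expect_equal(r$mean_after, mean(ts$temp_c[401:800]))
})

test_that("option b ignores a transient spike next to the candidate", {
  x <- c(rep(33, 200), rep(20, 200))
  x[196:199] <- 45  # spike in the last quarter of the before segment
  ts <- make_ts(x)
  cands <- make_cands(200, -1, ts)
  ra <- classify_option_a(ts, cands, 1)
  rb <- classify_option_b(ts, cands, 1)
  # arithmetic oracles
  expect_equal(ra$mean_before, mean(x[1:200]))
  expect_equal(rb$mean_before, mean(x[51:150]))
  expect_equal(rb$mean_before, 33)
  expect_gt(abs(ra$mean_before - 33), 0.2)
})

test_that("option c recovers steady levels across a slow transition", {
  # tau = 5 min; levels 33 -> 20; candidate at the transition
  prof <- make_exp_profile(c(33, 20), c(0, 14400), 28800, tau_s = 300)
  cands <- detect_candidates(temp_derivative(prof))
  expect_equal(nrow(cands), 1)
  r <- classify_option_c(prof, cands, 1)
  t_c <- cands$time_s[1]
  # independent window means by explicit time masks
  before <- prof$temp_c[prof$time_s >= t_c - 3600 & prof$time_s <= t_c - 600]
  after <- prof$temp_c[prof$time_s >= t_c + 600 & prof$time_s <= t_c + 3600]
  expect_equal(r$mean_before, mean(before))
  expect_equal(r$mean_after, mean(after))
  expect_equal(r$t_diff, 13, tolerance = 0.05)
  expect_true(r$retained)
})

test_that("option c flags candidates without usable windows", {
  ts <- step_series(c(33, 20), c(50, 1000))  # candidate 5 min from start
  cands <- make_cands(50, -1, ts)
  r <- classify_option_c(ts, cands, 1)
  expect_false(r$reliable)
  expect_false(r$retained)
})

test_that("option c truncates windows at a neighbouring candidate", {
  ts <- step_series(c(33, 26, 20), c(1200, 300, 1200))  # 30 min apart
  cands <- make_cands(c(1200, 1500), c(-1, -1), ts)
  r <- classify_option_c(ts, cands, 2)
  t1 <- cands$time_s[1]
  t2 <- cands$time_s[2]
  before <- ts$temp_c[ts$time_s >= t1 & ts$time_s <= t2 - 600]
  expect_equal(r$mean_before, mean(before))
})

test_that("bimoving walk finds the nearest trend extremum", {
  # monotone decreasing series: backward max walks to the series start
  x <- 33 - 0.005 * seq_len(2000)
  ts <- make_ts(x)
  r <- bimoving_extremum(ts, t_anchor = ts$time_s[1500], "backward",
                         mode = "max")
  expect_lt(r$t_extremum, 400)
  expect_equal(r$mean_w1, mean(x[1:50]), tolerance = 1e-9)

  # plateau then drop: backward max from the drop sits on the plateau
  prof <- make_exp_profile(c(33, 20), c(0, 5000), 20000, tau_s = 600)
  anchor <- prof$time_s[findInterval(5000, prof$time_s)]
  r <- bimoving_extremum(prof, anchor, "backward", mode = "max")
  expect_lt(r$t_extremum, 5000)
  expect_equal(r$mean_w1, 33, tolerance = 0.05)

  # forward min on the decay approaches the ambient level
  r <- bimoving_extremum(prof, anchor, "forward", mode = "min")
  expect_equal(r$mean_w1, 20, tolerance = 0.5)
})

test_that("bimoving walk agrees with the exhaustive window-scan oracle", {
  withr::with_seed(43, {
    for (rep in 1:20) {
      x <- 25 + cumsum(rnorm(600, 0, 0.1))
      ts <- make_ts(x)
      anchor_i <- sample(60:540, 1)
      for (dir in c("backward", "forward")) {
        for (mode in c("max", "min")) {
          got <- bimoving_extremum(ts, ts$time_s[anchor_i], dir,
                                   window_s = 300, mode = mode)
          expect_equal(got$mean_w1,
                       oracle_bimoving(x, anchor_i, dir, 50, mode),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("option d retains real removals and rejects ambient drift", {
  # plateau -> exponential drop -> plateau
  prof <- make_exp_profile(c(33, 20), c(0, 10800), 21600, tau_s = 600)
  cands <- detect_candidates(temp_derivative(prof))
  r <- classify_option_d(prof, cands, 1)
  expect_equal(r$t_diff, 13, tolerance = 0.3)
  expect_true(r$retained)

  # 1 degC/2h ambient drift with a small derivative blip: rejected
  drift <- make_ts(30 - seq(0, 1, length.out = 1200))
  cands <- make_cands(600, -1, drift)
  r <- classify_option_d(drift, cands, 1)
  expect_lt(r$t_diff, 3)
  expect_false(r$retained)
})

test_that("pruning pairs removals with reattachments", {
  ts <- step_series(c(33, 20, 33), c(600, 600, 600))
  cl <- make_classified(ts, c(600, 1200), c(-1, 1), c(-0.5, 0.5),
                        mean_before = c(33, 20), mean_after = c(20, 33))
  iv <- prune_events(cl, ts)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_s, ts$time_s[600])
  expect_equal(iv$end_s, ts$time_s[1200])
})

test_that("an interval whose temperature returns high is discarded", {
  # temperature pops back to skin level for 40 min mid-interval
  ts <- step_series(c(33, 20, 33, 20, 33), c(600, 100, 400, 100, 600))
  cl <- make_classified(ts, c(600, 1800), c(-1, 1), c(-0.5, 0.5),
                        mean_before = c(33, 20), mean_after = c(20, 33))
  iv <- prune_events(cl, ts)
  expect_equal(nrow(iv), 0)
  audit <- attr(iv, "audit")
  expect_true(all(audit$pruned_reason == "not_low"))
  # the corresponding epochs stay wear
  e <- intervals_to_epochs(iv, 1800 * 6, 60)
  expect_equal(sum(e$label), 0)
})

test_that("an interval that never reaches the low level is discarded", {
  ts <- step_series(c(33, 33, 33), c(600, 600, 600))
  cl <- make_classified(ts, c(600, 1200), c(-1, 1), c(-0.5, 0.5),
                        mean_before = c(33, 20), mean_after = c(20, 33))
  expect_equal(nrow(prune_events(cl, ts)), 0)
})

test_that("consecutive same-sign events keep the strongest peak", {
  ts <- step_series(c(33, 20, 33), c(600, 600, 600))
  cl <- make_classified(ts, c(600, 700, 1200), c(-1, -1, 1),
                        c(-0.3, -0.05, 0.5),
                        mean_before = c(33, 33, 20),
                        mean_after = c(20, 20, 33))
  iv <- prune_events(cl, ts)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_s, ts$time_s[600])  # stronger peak wins
  audit <- attr(iv, "audit")
  expect_equal(audit$pruned_reason[audit$index == 700], "alternation")
})

test_that("unmatched boundary events open or close at the series ends", {
  # trailing removal extends to the series end
  ts <- step_series(c(33, 20), c(600, 600))
  cl <- make_classified(ts, 600, -1, -0.5, 33, 20)
  iv <- prune_events(cl, ts)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$end_s, ts$time_s[1200] + 6)

  # leading reattachment implies the recording started off-body
  ts <- step_series(c(20, 33), c(600, 600))
  cl <- make_classified(ts, 600, 1, 0.5, 20, 33)
  iv <- prune_events(cl, ts)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_s, 0)
  expect_equal(iv$end_s, ts$time_s[600])
})

test_that("intervals split by a spurious pair over a low gap are merged", {
  ts <- step_series(c(33, 20, 33), c(600, 1200, 600))
  cl <- make_classified(
    ts, c(600, 1000, 1100, 1800), c(-1, 1, -1, 1),
    c(-0.5, 0.03, -0.03, 0.5),
    mean_before = c(33, 20, 20, 20),
    mean_after = c(20, 20, 20, 33)
  )
  iv <- prune_events(cl, ts)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_s, ts$time_s[600])
  expect_equal(iv$end_s, ts$time_s[1800])
  audit <- attr(iv, "audit")
  expect_setequal(audit$pruned_reason[audit$index %in% c(1000, 1100)],
                  "gap_not_high")
})

test_that("the assembled pipeline recovers simulated removals", {
  sim <- quick_temp_sim(101)
  ts <- preprocess_temp(sim$recording)
  ev <- detect_event(ts)
  truth_nw <- sim$truth[sim$truth$label == "nonwear", ]
  expect_equal(nrow(ev$intervals), nrow(truth_nw))
  # every detected boundary within 10 min of the matching true boundary
  expect_lt(max(abs(ev$intervals$start_s - truth_nw$start_s)), 600)
  expect_lt(max(abs(ev$intervals$end_s - truth_nw$end_s)), 600)
})

test_that("quiet recordings and pocket carriage yield no events", {
  no_events <- quick_temp_sim(102, schedule = tibble::tibble(
    start_s = numeric(), end_s = numeric(), label = character()
  ))
  ts <- preprocess_temp(no_events$recording)
  expect_equal(nrow(detect_event(ts)$intervals), 0)

  pocket_only <- quick_temp_sim(103, schedule = tibble::tibble(
    start_s = 30000, end_s = 34000, label = "pocket"
  ))
  ts <- preprocess_temp(pocket_only$recording)
  ev <- detect_event(ts)
  expect_equal(nrow(ev$intervals), 0)
  expect_equal(sum(ev$epochs$label), 0)  # pocket scored as worn
})

test_that("no events are retained when the true level change is small", {
  sim <- quick_temp_sim(104, ambient_day_c = c(30.6, 31.4),
                        ambient_out_c = c(30.6, 31.4))
  ts <- preprocess_temp(sim$recording)
  ev <- detect_event(ts)
  expect_equal(sum(ev$audit$retained), 0)
  expect_equal(nrow(ev$intervals), 0)
})

test_that("retention is monotone in the threshold", {
  sim <- quick_temp_sim(105)
  ts <- preprocess_temp(sim$recording)
  strict <- detect_event(ts, event_params(retain_thr_c = 5))
  loose <- detect_event(ts, event_params(retain_thr_c = 3))
  kept_strict <- strict$audit$cand[strict$audit$retained]
  kept_loose <- loose$audit$cand[loose$audit$retained]
  expect_true(all(kept_strict %in% kept_loose))
})

test_that("detected intervals are anchored on candidates and disjoint", {
  sim <- quick_temp_sim(106)
  ts <- preprocess_temp(sim$recording)
  ev <- detect_event(ts)
  iv <- ev$intervals
  if (nrow(iv) > 1) {
    expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)]))
  }
  minus_t <- ev$audit$time_s[ev$audit$sign == -1]
  plus_t <- ev$audit$time_s[ev$audit$sign == 1]
  t_end <- ts$time_s[nrow(ts)] + attr(ts, "dt_s")
  expect_true(all(iv$start_s %in% c(minus_t, ts$time_s[1])))
  expect_true(all(iv$end_s %in% c(plus_t, t_end)))
})
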