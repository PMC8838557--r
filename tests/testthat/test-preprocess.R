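# Band-passed vector magnitude, windowed SD, temperature decimation,
# Savitzky-Golay smoothing and the temperature derivative.

test_that("compiled IIR core reproduces signal::filter exactly", {
  withr::with_seed(2, {
    bf <- signal::butter(4, c(0.01, 0.4), type = "pass")
    x <- rnorm(500)
    nf <- max(length(bf$b), length(bf$a))
    b <- c(bf$b, rep(0, nf - length(bf$b)))
    a <- c(bf$a, rep(0, nf - length(bf$a)))
    got <- wearcheck:::iir_filter_cpp(b, a, x, rep(0, nf - 1))
    want <- as.numeric(signal::filter(bf, x))
    expect_equal(got, want, tolerance = 1e-9)
  })
})

test_that("vm_dynamic rejects gravity and preserves in-band motion", {
  fs <- 100
  n <- 60 * fs
  # static 1 g on z: dynamic VM is ~0 everywhere (no start-up transient
  # thanks to steady-state initial conditions)
  rec <- make_recording(rep(0, n), rep(0, n), rep(1, n), fs)
  y <- vm_dynamic(rec)$vm_g
  expect_lt(max(abs(y)), 1e-8)

  # 5 Hz, 0.1 g motion along the gravity axis: VM = 1 + a sin exactly, so
  # the filtered amplitude must match the squared Butterworth magnitude
  # response (zero-phase = two passes) at 5 Hz
  t <- (seq_len(n) - 1) / fs
  a <- 0.1
  rec <- make_recording(rep(0, n), rep(0, n), 1 + a * sin(2 * pi * 5 * t),
                        fs)
  y <- vm_dynamic(rec)$vm_g
  amp <- sd(y[(n / 4):(3 * n / 4)]) * sqrt(2)
  bf <- signal::butter(4, c(0.5, 20) / (fs / 2), type = "pass")
  hmag <- function(b, a_, w) {
    Mod(sum(b * exp(-1i * w * (seq_along(b) - 1))) /
          sum(a_ * exp(-1i * w * (seq_along(a_) - 1))))
  }
  h <- hmag(bf$b, bf$a, 2 * pi * 5 / fs)^2
  expect_equal(amp, a * h, tolerance = 0.02)

  # 0.05 Hz slow tilt: below the band, attenuated by >= 20 dB
  rec <- make_recording(0.2 * sin(2 * pi * 0.05 * t), rep(0, n), rep(1, n),
                        fs)
  y <- vm_dynamic(rec)$vm_g
  in_amp <- sqrt(2) * sd(sqrt((0.2 * sin(2 * pi * 0.05 * t))^2 + 1))
  expect_lt(sd(y[(n / 4):(3 * n / 4)]) * sqrt(2), in_amp / 10)

  expect_error(vm_dynamic(rec, fc2 = 60), class = "wearcheck_config_error")
})

test_that("windowed_std uses the population denominator on fixed windows", {
  # hand-computable case: one window of 4 samples, denominator n
  got <- windowed_std(c(1, 2, 3, 4), window_s = 4, fs = 1)
  expect_equal(got$sd_g, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))

  expect_equal(windowed_std(rep(2.5, 600), window_s = 60, fs = 1)$sd_g,
               rep(0, 10))

  # zero-mean sinusoid, whole cycles per window: SD -> A / sqrt(2)
  fs <- 100
  t <- (seq_len(60 * fs) - 1) / fs
  s <- 0.2 * sin(2 * pi * 5 * t)
  expect_equal(windowed_std(s, window_s = 60, fs = fs)$sd_g,
               0.2 / sqrt(2), tolerance = 1e-3)

  # white noise, 6000 samples per window: within 3% of sigma
  withr::with_seed(4, {
    x <- rnorm(6000, 0, 0.05)
    expect_equal(windowed_std(x, window_s = 60, fs = 100)$sd_g, 0.05,
                 tolerance = 0.03)
  })

  expect_warning(empty <- windowed_std(1:10, window_s = 60, fs = 1),
                 "shorter")
  expect_equal(nrow(empty), 0)
})

test_that("windowed_std is invariant to adding a constant", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      x <- rnorm(3000)
      expect_equal(
        windowed_std(x, window_s = 10, fs = 50)$sd_g,
        windowed_std(x + runif(1, -30, 30), window_s = 10, fs = 50)$sd_g,
        tolerance = 1e-9
      )
    }
  })
})

test_that("downsample_temp keeps every factor-th sample", {
  ts <- make_ts(seq(30, by = 0.01, length.out = 600), dt_s = 1,
                smoothed = FALSE)
  d6 <- downsample_temp(ts, 6)
  expect_equal(nrow(d6), 100)
  expect_equal(attr(d6, "dt_s"), 6)
  expect_equal(d6$temp_c, ts$temp_c[seq(1, 600, by = 6)])

  expect_equal(downsample_temp(ts, 1)$temp_c, ts$temp_c)
  expect_error(downsample_temp(ts, 0), class = "wearcheck_config_error")

  # ramp slope per second is unchanged by decimation
  slope <- diff(d6$temp_c) / diff(d6$time_s)
  expect_equal(slope, rep(0.01, 99), tolerance = 1e-9)

  # composition: factors a then b == factor a*b
  expect_equal(downsample_temp(downsample_temp(ts, 2), 3)$temp_c,
               downsample_temp(ts, 6)$temp_c)
})

test_that("smooth_temp reproduces low-degree polynomials and is linear", {
  t <- seq_len(200)
  ramp <- make_ts(20 + 0.05 * t, smoothed = FALSE)
  sm <- smooth_temp(ramp)
  expect_equal(sm$temp_c[20:180], ramp$temp_c[20:180], tolerance = 1e-9)

  cubic <- make_ts(20 + 0.01 * t - 2e-4 * t^2 + 1e-6 * t^3,
                   smoothed = FALSE)
  expect_equal(smooth_temp(cubic)$temp_c[20:180], cubic$temp_c[20:180],
               tolerance = 1e-9)

  withr::with_seed(3, {
    x <- make_ts(rnorm(150), smoothed = FALSE)
    y <- make_ts(rnorm(150), smoothed = FALSE)
    lhs <- smooth_temp(make_ts(2 * x$temp_c - 3 * y$temp_c,
                               smoothed = FALSE))$temp_c
    rhs <- 2 * smooth_temp(x)$temp_c - 3 * smooth_temp(y)$temp_c
    expect_equal(lhs, rhs, tolerance = 1e-9)
  })

  expect_error(smooth_temp(ramp, window_samples = 10), "odd")
  expect_error(smooth_temp(make_ts(1:5, smoothed = FALSE),
                           window_samples = 11), "longer")
})

test_that("smoothing suppresses alternating noise but keeps steps sharp", {
  t <- seq_len(400)
  noise <- 0.05 * rep_len(c(1, -1), 400)
  noisy <- make_ts(20 + 0.01 * t + noise, smoothed = FALSE)
  resid <- smooth_temp(noisy)$temp_c - (20 + 0.01 * t)
  expect_lt(max(abs(resid[20:380])), 0.05 / 5)

  step <- make_ts(c(rep(30, 200), rep(20, 200)), smoothed = FALSE)
  sm <- smooth_temp(step)$temp_c
  # midpoint crossing stays within 2 samples of the true transition
  crossing <- which(sm < 25)[1]
  expect_lte(abs(crossing - 200.5), 2.5)
})

test_that("temp_derivative is the first difference", {
  expect_equal(temp_derivative(make_ts(rep(21, 50)))$dtemp_c, rep(0, 49))
  ramp <- make_ts(seq(20, by = 0.03, length.out = 50))
  d <- temp_derivative(ramp)
  expect_equal(d$dtemp_c, rep(0.03, 49), tolerance = 1e-12)
  expect_equal(nrow(d), 49)
  expect_error(temp_derivative(make_ts(21)), "short")
})

test_that("a realistic removal transient yields the expected weak peak", {
  # 13 degC drop with the sensor's slow in-situ response: the derivative
  # peak lands in the 0.01-0.02 degC-per-sample range that motivates the
  # deliberately low candidate threshold
  prof <- make_exp_profile(c(33, 20), c(0, 7200), 36000, tau_s = 5000)
  sm <- smooth_temp(make_ts(prof$temp_c, smoothed = FALSE))
  d <- temp_derivative(sm)
  peak <- max(abs(d$dtemp_c))
  expect_gte(peak, 0.01)
  expect_lte(peak, 0.02)
})
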