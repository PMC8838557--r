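# wearcheck

Non-wear time detection for body-worn activity monitors that record 3-axis
acceleration together with device temperature.

## The problem

Before any physical-activity analysis, the periods in which a device was
not actually worn must be removed: a monitor lying on a shelf produces a
weak signal that activity classifiers happily score as sedentary time or
sleep. Acceleration alone cannot make the distinction — a sleeping wearer
and a shelved device look nearly identical — so accelerometer-only
detectors systematically misclassify sleep and long sedentary periods as
non-wear, and ignore every removal shorter than their 30-min grouping
window.

`wearcheck` adds the device temperature channel. Worn against the skin,
the sensor sits near skin temperature (~33 °C); removed, it relaxes
exponentially towards the ambient temperature of wherever it was left.
The package implements:

* **`detect_event()`** — the event-based temperature detector at the core
  of the package. Candidate removal/reattachment events are peaks in the
  derivative of the smoothed, decimated temperature signal
  (|dT| ≥ 0.02 °C/sample); a candidate is retained when the temperature
  *level* changes by at least 3 °C across it,
  `T_diff = |mean(T_bef) − mean(T_aft)| ≥ 3 °C`, with the levels measured
  by one of four windowing options — option *d* (default) places a 5-min
  averaging window at the nearest local extremum of the temperature trend
  on each side, found by a bi-directional moving-window walk. A pruning
  stage enforces removal→reattachment alternation and checks the
  temperature stays low while the device is off. Because the 3 °C
  criterion is *relative*, the detector transfers across climates and
  devices — unlike absolute-threshold methods.
* **`detect_window()`** — window-based baselines: mean temperature per
  1-min window against a fixed 18 °C threshold or an adaptive midpoint
  threshold derived from it.
* **`detect_accel()`** — the accelerometer standard: SD of the band-passed
  (0.5–20 Hz Butterworth) vector magnitude per minute against 13 mg, with
  non-wear runs under 30 min ignored.
* **`combine_and()`** — AND-fusion of the two modalities on the shared
  epoch grid.
* **`confusion()` / `aggregate_metrics()`** — epoch-level SEN/SPE/ACC/NPV
  under the positive = wear convention, per recording and aggregated as
  mean (SD).
* **`sim_scenario()` / `simulate_recording()` / `protocol_batch()`** — a
  ground-truthed simulator of multi-day wear protocols (daily short
  removals, a long removal, pocket carriage, wrong-orientation
  reattachment, nightly sleep) with first-order thermal relaxation and
  state-driven acceleration variance.

Everything is tibble-in/tibble-out and pipe-friendly; fitted result
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate one day of a monitored participant (two removals: a ~27-min and a
~2-h one), then detect non-wear from the temperature channel alone:

```r
library(wearcheck)

sim <- simulate_recording(sim_scenario(duration_s = 86400, seed = 42))
sim$truth
#> # A tibble: 2 × 3
#>   start_s  end_s label
#>     <dbl>  <dbl> <chr>
#> 1   8648. 10285. nonwear
#> 2  21442. 28504. nonwear

ev <- sim$recording |> preprocess_temp() |> detect_event(option = "d")
ev
#> <wear_events> option d: 1248 candidates -> 166 retained -> 2 non-wear interval(s), 145.1 min non-wear
ev$intervals
#> # A tibble: 2 × 3
#>   start_s end_s label
#>     <dbl> <dbl> <chr>
#> 1    8685 10323 nonwear
#> 2   21465 28533 nonwear
```

Both removals are recovered with boundaries within ~40 s of the truth (the
residual lag is the sensor's thermal response: the derivative peaks sit on
the slope, not at its foot). Score it, and the accelerometer baseline,
against the ground truth on the 1-min epoch grid:

```r
truth <- intervals_to_epochs(sim$truth, duration_s = 86400)
glance(confusion(ev$epochs, truth))
#> # A tibble: 1 × 10
#>      tp    fp    tn    fn masked n_epochs   sen   spe   acc   npv
#>   <int> <int> <int> <int>  <int>    <int> <dbl> <dbl> <dbl> <dbl>
#> 1  1293     2   143     2      0     1440 0.998 0.986 0.997 0.986

acc_epochs <- sim$recording |> vm_dynamic() |> windowed_std() |> detect_accel()
glance(confusion(acc_epochs, truth))
#> # A tibble: 1 × 10
#>      tp    fp    tn    fn masked n_epochs   sen   spe   acc   npv
#>   <int> <int> <int> <int>  <int>    <int> <dbl> <dbl> <dbl> <dbl>
#> 1   867    27   118   428      0     1440 0.669 0.814 0.684 0.216
```

The contrast is the package's core story: the temperature event detector
scores ≥ 0.98 on every metric, while the accelerometer mislabels the
~7 h of sleep as non-wear (428 false-negative epochs → sensitivity 0.67,
NPV 0.22), exactly the failure mode that motivates putting temperature
into the equation.

Multi-algorithm comparisons over a simulated batch:

```r
res <- run_compare(list(n = 16, seed = 1,
                        algorithms = c("accel", "temp-event-d", "combined")))
res$summary     # mean (SD) per metric and algorithm
autoplot(res)   # grouped bar chart
```

A thin command-line wrapper over the same functions lives in
`inst/cli/wearcheck` (subcommands `simulate`, `detect`, `evaluate`,
`compare`; exit codes 0/2/3 for success/config error/data error).

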