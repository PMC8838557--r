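---
title: "Detecting non-wear time from acceleration and device temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-wear time from acceleration and device temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term physical-activity monitoring with body-worn devices is only as
reliable as its pre-processing: periods during which the device was not
actually worn must be found and excluded, or the weak signal recorded while
the device lies on a shelf is scored as sedentary time or sleep and biases
every downstream outcome. The difficulty is that genuine inactivity — an
older adult sitting still for two hours, or anyone asleep — produces almost
the same acceleration signal as a device lying on a table. Acceleration
alone cannot separate the two cases, which is exactly where the classical
detectors fail.

Devices that also log their own temperature offer a second, independent
physical signal. Worn against the skin the sensor sits near skin-contact
temperature (around 33 °C at the lower back); removed, it relaxes towards
the ambient temperature of wherever it was left. `wearcheck` implements and
compares the detector families built on these two signals, with the
event-based temperature detector — which uses a *relative* 3 °C temperature
change rather than any absolute threshold — as its centrepiece.

## The detectors

### Accelerometer baseline (`detect_accel`)

The vector magnitude $\mathrm{VM} = \sqrt{a_x^2+a_y^2+a_z^2}$ is band-pass
filtered (4th-order Butterworth, 0.5–20 Hz, applied forward–backward so no
phase lag is introduced) to isolate the dynamic, gravity-free component of
movement. Its standard deviation over 1-min windows is compared with
thr = 13 mg — a threshold covering the electrical noise floor of common
MEMS accelerometers — and provisional non-wear minutes are kept only in
runs of at least 30 min, the standard guard against motion-artifact
misclassification. Two consequences follow directly from the construction:
removals shorter than 30 min are invisible, and every long still period
(sleep above all) is a false non-wear call. Both are reproduced
quantitatively by the simulator (see below).

Numerical details fixed by the implementation: the SD uses denominator $n$
(population form; at 6000 samples per window the difference from $n-1$ is
negligible but the convention must be pinned for exact tests); a window SD
exactly equal to the threshold counts as wear (strict `<`); runs touching
the recording boundaries are subject to the same 30-min rule; the
zero-phase filter uses odd-reflection padding with steady-state initial
conditions, so a constant input produces a constant (zero) output with no
start-up transient.

### Window-based temperature baselines (`detect_window`)

The state-of-the-art absolute-threshold approach: the temperature series is
scanned in 1-min windows and a window whose mean is strictly below a
threshold is non-wear. Two threshold policies are provided behind the same
scanning code, so the policy is the only difference being compared: a
**fixed** threshold at 18 °C, and an **adaptive** variant that splits the
recording's samples at 18 °C, averages each side, and moves the threshold
to the midpoint of the two means (samples exactly at 18 °C join neither
side; if the whole recording lies on one side the threshold falls back to
18 °C with a warning flag). The adaptive rule helps when the climate shifts
the whole distribution, but it inherits the absolute anchor: if ambient
temperatures sit mostly *above* the anchor, the split is lopsided and the
midpoint lands away from the valley between the ambient and skin modes.
Both variants fail structurally once ambient temperature exceeds the
threshold — the device can then never cool below it — which is the
portability problem the event-based method removes.

### Event-based temperature detection (`detect_event`)

The temperature channel is first decimated by 6 (the sensor's own thermal
response, with a steady state reached in roughly 6 s, means faster samples
carry only quantisation chatter; decimation also concentrates each
transition's temperature change into fewer samples, enlarging its
derivative peak) and smoothed with a Savitzky–Golay filter, which
suppresses noise while passing local polynomials — hence sudden level
changes — through undistorted. On the first difference of this series,
device removal appears as a negative excursion and reattachment as a
positive one, but with amplitudes of only 0.01–0.02 °C per sample for slow
sensors, too weak for direct thresholding against fluctuations.

The detector therefore separates *detection* from *classification*:

1. **Candidates.** Every maximal same-sign excursion of the derivative with
   $|d| \ge 0.02$ °C/sample contributes one candidate (its
   largest-magnitude sample). The threshold is deliberately low: it must
   catch every plausible transition; discrimination happens later.
2. **Classification.** For each candidate the temperature *level* before
   and after it is estimated and the candidate is retained when
   $T_{\mathrm{diff}} = |\overline{T}_{\mathrm{bef}} -
   \overline{T}_{\mathrm{aft}}| \ge 3\,°C$ (a change of exactly 3 °C is
   retained; the tie is pinned by a test). Four windowing options are
   provided: (a) the whole segment to the neighbouring candidates, (b) the
   central half of each segment, (c) fixed 60-min windows skipping the
   10 min adjacent to the candidate so the sensor can settle, and (d) a
   5-min window placed at the nearest local extremum of the temperature
   trend on each side, found by walking two adjacent moving-average
   windows (W1 nearer the anchor, W2 beyond it) away from the candidate
   while the trend still rises/falls towards it. Option (d) is the default:
   it measures the level exactly at the plateaus the transition connects,
   making it robust both to distant candidate spacing and to slow
   transients.
3. **Pruning.** Retained events must alternate removal → reattachment, and
   the temperature must stay low while the device is off. Each surviving
   (−, +) pair becomes a non-wear interval; an unmatched final removal
   runs to the end of the recording, and a leading unmatched reattachment
   opens an interval from the recording start (the series is otherwise
   assumed to start in the wear state).

Because retention compares *relative* levels, nothing in the pipeline
depends on the local climate or on the sensor's absolute calibration — the
property that makes the method portable across studies, seasons and
devices.

### Fusion (`combine_and`)

The combined classifier labels an epoch non-wear only when the
accelerometer and temperature conditions hold simultaneously — an
element-wise AND on the shared 1-min epoch grid. It can only shrink the
non-wear set, so false alarms unique to one sensor are vetoed, but misses
are inherited from both: with the accelerometer blind to sub-30-min
removals, the combination loses the short removals the temperature channel
finds, and its specificity drops accordingly.

## Design choices in the pruning stage

The pruning rules as stated in the literature are sparse, and three
operationalisations had to be fixed. They are the package's own choices:

* **"Temperature remained low" test.** A non-wear interval's reference low
  level is the removal's after-level (from the classification stage). The
  naive rule "no sample may exceed low + 3 °C" would discard *every*
  genuine event, because the relaxation tails at both ends of a real
  interval necessarily pass through any such level. The implemented rule:
  the signal must reach low + 3 °C at some point, and after first reaching
  it may not stay above that level for longer than one bi-moving window
  (5 min). A mid-interval return to skin temperature — the signature of a
  spurious event — always violates this; the end-of-interval rewarming
  tail (about a minute between reattachment and its detected peak) never
  does.
* **Alternation repair.** When two retained events of the same sign are
  adjacent, the one with the larger derivative magnitude is kept. Sensor
  noise can split the long supra-threshold excursion of one removal into
  fragments, yielding trailing same-sign candidates well down the slope;
  their bi-moving level estimates tie the main peak's (both walks reach the
  same plateaus), so a $T_{\mathrm{diff}}$-based repair would pick between
  them at random and can mislocate the boundary by tens of minutes. The
  derivative amplitude separates the true transition from its fragments by
  an order of magnitude.
* **Low-gap merging.** Symmetrically to the "remained low" test, two
  detected intervals separated by a supposed wear gap in which the
  temperature never rises above low + 3 °C are merged: the intervening
  reattach/removal pair was spurious — the device demonstrably stayed
  cold, hence off. Without this rule an opposite-sign noise candidate
  inside a long non-wear interval splits it in two.

Other pinned choices: candidate runs are split on sign changes even without
a sub-threshold gap between them; option (b)'s "middle of the segment" is
the central 50%; option (c) abstains (candidate not retained) when the
neighbour-clipped windows contain no samples — under densely packed noise
candidates this makes option (c) conservative to the point of detecting
nothing, a documented limitation of that variant rather than of the event
framework; the bi-moving walk advances in steps of one window length and
accepts a boundary window as the extremum when the series ends first.

## Scoring

All detectors are reduced to a common grid of 1-min epochs (0 = wear,
1 = non-wear; an epoch is non-wear when more than half its span is covered,
so exactly half stays wear). Metrics follow the positive = wear convention:
sensitivity is the fraction of true wear epochs called wear, specificity
the fraction of true non-wear epochs called non-wear, NPV the fraction of
predicted non-wear that is truly non-wear, and accuracy the overall
fraction correct. Ratios with a zero denominator are reported as absent,
never as zero, and aggregation over recordings is the unweighted mean and
sample SD per metric, skipping absences. Pocket-carriage epochs count as
wear by default — the device *is* on the body and every algorithm treats it
as worn — with `pocket_as = "nonwear"` or `"exclude"` (masking) available
for sensitivity analyses.

## What the simulator emulates — and what it does not

`sim_scenario()`/`simulate_recording()` generate ground-truthed 3-day
recordings (100 Hz acceleration, 1 Hz temperature) built around the
physical structure the detectors exploit.

* **Thermal model.** The device temperature follows first-order (Newton)
  relaxation towards skin temperature (33 °C) while worn or carried in a
  pocket, and towards the event's storage ambient while off, with
  τ = 5 min after attachment and τ = 10 min after removal — constants
  chosen so transients settle within the 10-min steady-state allowance of
  classification option (c). Gaussian sensor noise (SD 0.05 °C) is added
  per sample.
* **Protocol.** Each day contains a short (20–50 min) removal stored
  indoors (18–23 °C) plus a second task cycling over: a long (1.5–3 h)
  removal and a wrong-orientation removal (20–45 min), both stored at the
  outdoor-range ambient (−3 to 17 °C by default), and a pocket-carriage
  interval (40–90 min) during which the temperature target remains skin
  level. Nightly sleep blocks last 7–9 h. Task times are drawn inside
  disjoint windows so events can never collide.
* **Acceleration.** Per-minute behavioural states drive the axis noise SD:
  active wear 0.05–0.3 g, sedentary wear and sleep 0.001–0.008 g, static
  non-wear at the 2 mg sensor noise floor, pocket carriage a mixture of
  active-like and quiet minutes. Daytime wear alternates activity bouts
  (2–10 min) with sedentary bouts (8–25 min) — deliberately shorter than
  the 30-min rule — while sleep contains only sparse posture shifts every
  40–100 min, so sustained sub-threshold runs occur almost exclusively in
  sleep. The minute flanking each removal/reattachment carries handling
  movement (the clap-synchronisation ritual), which also separates quiet
  wear from non-wear runs. Wrong-orientation reattachment permutes the
  gravity axis and nothing else: it must not trigger any detector, and the
  vector-magnitude pipeline is orientation-invariant by construction.
* **Determinism.** A simulation is a pure function of its scenario,
  including the seed. Schedule, temperature noise and acceleration noise
  use independently derived seeds, so the temperature channel is
  bit-identical whether or not the (much larger) acceleration channel is
  generated — the batch evaluations exploit this to keep temperature-only
  comparisons cheap.

The simulator does **not** model circadian skin-temperature variation,
ambient drift within a non-wear event, device clock drift, water exposure,
or the heavier-tailed noise of real accelerometers during transport. Tests
passing on simulated data therefore demonstrate the algorithms' mechanics
under the stated physics — thresholds separating the constructed SD ranges,
relaxation reaching ambient within a few τ — not their field performance,
which in the source study could only be established against diary-annotated
real recordings.

## Problem sizes and validation design

The protocol-scale checks run two batches of 16 simulated 3-day
recordings: one under the default cool storage ambients and one with every
ambient raised to 20–22 °C. On the default batch the event-based detector
(option d) is required to reach mean SEN ≥ 0.97, SPE ≥ 0.90, ACC ≥ 0.95
and NPV ≥ 0.90 with every detected boundary within 10 min of the truth;
the accelerometer detector must trail it on SEN and NPV with at least 80%
of its false-negative epochs inside sleep; and between the two batches the
fixed-18 °C window detector must lose at least 20 specificity points while
the event-based detector moves by less than 5. The warm batch exercises
only the temperature channel. `scripts/acceptance.R` recomputes all of
these quantities from scratch; unit-level properties (oracle equivalences,
tie semantics, pruning edge cases) live in the test suite with
deliberately small fixtures.

## Known limitations

* Boundary timing inherits the sensor's thermal lag: derivative peaks sit
  on the slope, about one to two minutes after the physical transition for
  the simulated constants, and longer for slower sensors.
* A removal into an environment within 3 °C of skin temperature (pocket
  carriage being the extreme case) is invisible to all temperature methods;
  by design such periods score as wear.
* Option (c) abstains under densely spaced candidates (noisy derivative);
  use option (d) on low-SNR temperature channels.
* The ×6 decimation is matched to a sensor whose thermal response settles
  in about 6 s; other hardware warrants re-tuning `factor` and the
  Savitzky–Golay window (both are exposed parameters, defaults 6 / 11
  samples / order 3).
* Back-to-back removal–reattach cycles shorter than the 5-min bi-moving
  window merge into a single event or escape detection entirely.
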