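---
title: "Detecting non-wear from temperature rate-of-change and acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-wear from temperature rate-of-change and acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detachr)
```

## The problem

Wrist-worn accelerometers are used to estimate physical activity, sleep and
sedentary behaviour from days of continuous free-living recording.  When the
wearer takes the device off — a shower, a swim, simple forgetfulness — the
signal looks deceptively like sleep or quiet sitting: little to no movement.
Mislabelling those gaps inflates sedentary and sleep estimates and corrupts
wear-time compliance measures, which matters most in clinical populations
where small behavioural changes carry diagnostic weight.

Acceleration-only detectors handle this by demanding a long motionless
window (classically 60 minutes) before declaring non-wear, which makes them
blind to short removals — yet most real removals are shorter than an hour.
Devices with a near-body temperature sensor offer a second channel: worn
against skin the sensor reads roughly 28–31 °C; off the wrist it relaxes
toward ambient.  An absolute temperature threshold (26 °C in the classic
combined algorithm) exploits this but reacts slowly — the device needs many
minutes to cool that far — and misbehaves in cold environments.

The detector at this package's core instead keys on the *rate of change* of
temperature: removal produces a characteristic cooling edge on the order of
−0.4 °C/min within the first five minutes, and re-donning a warming edge of
similar magnitude, regardless of where the absolute temperature sits.
Combining those edges with per-axis rolling acceleration statistics yields
interval detection with a resolution of minutes rather than an hour.

## Signals and features

A recording couples tri-axial acceleration (gravity units, nominally 75 Hz,
±8 g) with near-body temperature (°C, nominally 0.25 Hz) under one start
time (`raw_recording()`, EDF or long-CSV serialization).  All detectors
consume a 0.25 Hz feature grid (`extract_features()`):

* **Smoothed temperature** — an order-2 low-pass Butterworth filter with a
  0.005 Hz cut-off.  Filtering is zero-phase (forward–backward) by default:
  analysis is offline, and a causal pass would shift every temperature edge
  by the filter's group delay, biasing detected boundaries late.  A causal
  single pass is available (`zero_phase = FALSE`) for streaming parity.
  Both passes use odd-reflection padding with steady-state initial
  conditions, so a constant series is reproduced exactly (unit DC gain) and
  edge transients do not leak into the first minutes of a recording.
* **Per-axis rolling SD** — the population standard deviation of each
  acceleration axis over a 60 s window, in milligravity (mg), evaluated on
  the 0.25 Hz grid.  The window is *forward-looking*: the value stamped at
  `t` summarizes `[t, t + 60 s)`.  The rules below speak of "the following
  minute", and a forward convention lets rule code index the feature at the
  candidate instant directly.  Population rather than sample SD: with 4500
  samples per window the distinction is far below threshold resolution, and
  it keeps the brute-force oracle used in the tests trivial.
* **Temperature rate-of-change** — the forward difference quotient
  `(T(t + lag) − T(t)) / lag` in °C/min at lags of 1 and 5 minutes, masked
  where the look-ahead leaves the recording.  The 5-minute variant is the
  difference quotient over the full lag, not the mean of five 1-minute
  rates; the two differ only by telescoping error on the smoothed signal,
  and the difference quotient is the directly testable definition.

## The detection rules

Non-wear **starts** at the first grid instant where the acceleration is
quiet — at least 2 axes with rolling SD < 8 mg now, and that condition
holding on at least 90% of the following 5 minutes (the 90% tolerance
absorbs brief bumps of a resting device) — and the temperature evidence
fires on either pathway:

* *rate pathway*: 5-minute rate-of-change ≤ −0.2 °C/min while the absolute
  temperature is below 30 °C, or
* *low-temperature pathway*: absolute temperature below 26 °C, for removals
  that begin with the device already near a cool ambient.

Non-wear **ends** at the first instant, at least one confirmation window
after the start, where movement resumes — all three axes > 8 mg over the
previous minute and at least 2 axes > 8 mg on at least 50% of the following
5 minutes — and either the 5-minute rate exceeds +0.1 °C/min or the
absolute temperature exceeds 26 °C.  When both start pathways fire at one
instant the rate pathway is recorded (the low path is the one with the
documented false-positive excess); an interval still open at the end of the
recording is emitted with `end_path = "recording_end"` rather than dropped,
since recordings are routinely cropped at a final removal.

Inequalities are implemented exactly as printed for the rule set: start SD
strictly `< 8` mg, start rate `≤ −0.2` (a *minimum* decrease, so equality
fires), absolute gate `< 30`, end SDs `> 8`, end rate `> 0.1`, low path
`< 26`, high path `> 26`.  The scan runs left to right on the feature grid;
re-arming after an end requires one feature period.  Boundaries are
multiples of the 4 s grid, so they are already whole seconds for
evaluation.  If an end's 5-minute look-ahead is truncated by the recording
end, the available fraction is used at the same thresholds.

The thresholds originate from a depth-3 CART analysis (raw values: rate
−0.27 °C/min, x-axis SD ≤ 7 mg, absolute temperature ≤ 29.5 °C for starts;
x-axis SD ≥ 17 mg and z-axis SD ≥ 138 mg for ends), generalized to
axis-count form and rounded; the raw constants are retained in
`detach_params()$cart_raw` for provenance, and the `fit_cart()` /
`build_training_table()` utilities reproduce the discovery procedure on
synthetic data.

## Comparators

`vanhees_detect()` re-implements the acceleration-only standard: 60-minute
windows every 15 minutes, a window being non-wear when at least two axes
have SD < 13 mg *or* range < 50 mg; windows project to per-second labels by
union (a second is non-wear if any covering window is), and wear runs
shorter than 6 h (resp. 3 h) flanked by non-wear are reclassified when
shorter than 30% (resp. 80%) of the bordering non-wear, each rule applied
once, left to right.  The union projection and single-pass rule application
are conventions chosen here; union is the common projection in this
algorithm family and maximizes the 15-minute step's resolution, and a flag
(`iterate_rules`) exposes fixpoint iteration for sensitivity analysis.
Whether the SD and range criteria must hold on the *same* two axes is
ambiguous in the published summaries; each axis here satisfies
(SD < 13 mg OR range < 50 mg) and axes are then counted.

`zhou_detect()` re-implements the combined-sensor comparator: non-wear on a
one-minute window when mean temperature ≤ 26 °C and either all three axes
have SD < 13 mg, or the mean temperature fell relative to the previous
window.  Temperature is smoothed with a one-minute moving average (the
smoothing this algorithm was published with) rather than the Butterworth
filter; windows step without overlap.

## Evaluation

Scoring is duration-weighted at one-second resolution: intervals become
per-second labels under half-open `[start, end)` semantics (a second
straddling a sub-second boundary is labelled by majority coverage), and the
confusion matrix counts seconds with non-wear as the positive class.
Metrics follow the standard formulas — precision TP/(TP+FP), recall
TP/(TP+FN), F1 the harmonic mean, accuracy (TP+TN)/total — with 0/0 cases
reported as *absent* rather than imputed to zero; a participant who never
removed the device has no defined recall, and pretending otherwise biases
aggregates.  Aggregation is an equal-weighted across-participant mean with
a t-distribution 95% interval clipped to [0, 1]; clipping matters because
near-ceiling metrics routinely produce raw upper bounds above 1.

## The synthetic validation model

The reference data behind the original study sit behind a data-access
agreement, so validation here runs on a generative model
(`synthetic_config()`, `generate_recording()`, `scenario_battery()`) whose
defaults encode the reported cohort statistics:

* **Thermodynamics** — Newtonian relaxation at 0.25 Hz toward a
  state-dependent target: skin minus a 2 °C contact offset during wear
  (skin drawn per participant from N(31, 1.5²), so worn temperature is
  ≈ 29 ± 2 °C), ambient (default 21 °C) during non-wear with constant
  0.045/min (≈ −0.4 °C/min initial slope at a typical gap), and back toward
  the wear target at 0.04/min after re-donning; AR(1) measurement noise
  (coefficient 0.9, stationary SD 0.1 °C) — white noise at 0.25 Hz would
  make smoothed rates unrealistically clean.
* **Removals** — log-normal durations (median 23 min, σ_log = 0.906 so
  ≈ 85.5% fall under an hour, clamped to 3–240 min), placed in wake time.
  Each removal is preceded by a 15-minute active bout and a brief high-SD
  handling burst (taking the device off), and followed by handling plus an
  active bout that lasts until the modelled device temperature clears
  26.5 °C (capped at 35 min): a wearer re-dons the device mid-activity, and
  without that behavioural coupling every re-donning would be followed by
  ~20 minutes of sub-26 °C wear in which any sedentary bout trips the
  low-temperature pathway, making clean single-interval recovery of a
  removal impossible by construction.
* **Activity** — wake time partitions into sedentary (2–6 mg per-axis SD),
  light (10–40 mg) and active (50–300 mg) bouts of 10–45 min, with a
  gravity-oriented unit baseline re-drawn at bout boundaries and frozen
  during non-wear.  Two sedentary bouts never run back to back, bounding
  motionless wear runs well under the comparator's 60-minute window.
  Undisturbed non-wear carries only a 0.3 mg sensor noise floor; bumps
  (10–25 s, 15–30 mg, 0.5/h of non-wear) are placed in the interior of
  removals of at least 30 min, no closer than 7 min to the start — the
  clearance a forward-looking 60 s window plus 5-minute confirmation needs
  for bumps to be an interior phenomenon rather than an edge one.
* **Sleep** — quiet blocks with a warm, stable target (30.5–32.5 °C, above
  the 30 °C start gate) reached and left slowly: the post-sleep drift back
  to the wear baseline is capped at 0.045 °C/min *downward*, so waking
  never mimics a removal's cooling edge.  This encodes the sleep-vs-removal
  discriminability that motivates the rate criterion.

Named batteries (`standard`, `cold_ambient`, `sleep_heavy`,
`short_removals`, `bumped_nonwear`) derive one RNG stream per recording
from the master seed and participant index, so batteries are extensible
without perturbing earlier members, and generation is bit-reproducible.

What the model does *not* emulate: circadian temperature structure,
posture- and gait-specific acceleration, device-specific noise floors,
annotation error in the reference (ground truth is exact), and ambient
temperature drift within a recording.  Passing the synthetic batteries
therefore demonstrates that the implementation realizes the published rules
and their qualitative behaviour — short-removal resolution, sleep
robustness, cold-ambient precision relative to the absolute-threshold
comparator — not that the printed cohort metrics would be reproduced on the
restricted data.

## Problem sizes and numerical choices

The validation batteries are 10 recordings × 24 h per scenario; unit tests
use minutes-to-hours fixtures.  Rolling statistics are computed from
centred cumulative sums (the per-axis mean is subtracted first), which
keeps the rolling SD within 10⁻⁶ mg of a two-pass oracle across the tested
range.  Variances are clamped at zero before the square root.  CART splits
search midpoints of adjacent distinct values exhaustively, minimizing
weighted Gini impurity (entropy by flag), ties broken by lowest feature
index then lowest threshold, depth capped at 3 with no pruning.  EDF
serialization uses 16-bit quantization over each channel's declared
physical range (±8 g for acceleration; a per-file range covering the data
for temperature), i.e. ≈ 0.24 mg and < 10⁻⁴ °C steps.

## Known limitations

Two behaviours of the published rule set surface repeatedly on synthetic
cohorts and bound the boundary accuracy one should expect:

* **Warm wearers.** The rate pathway requires absolute temperature < 30 °C
  at the candidate instant.  A participant whose worn device sits above
  ~31 °C cannot trigger a start until the device has cooled below 30 °C,
  which at typical indoor gaps takes 3–5 minutes; starts for such
  participants are systematically late by that amount.  The original cohort
  contained start temperatures up to 34 °C, so this is a property of the
  algorithm, not of the re-implementation.
* **Cool wearers.** A wear baseline near 26 °C leaves the low-temperature
  pathway armed during ordinary sedentary wear, particularly in the
  tens of minutes of re-warming after each re-donning; these produce
  false-positive intervals that end only when movement resumes alongside
  warming.  The same failure mode is documented for the original algorithm,
  where the low path contributed a disproportionate share of false
  positives.

Both are visible in the packaged acceptance checks and are left visible by
design: they delimit where a rate-of-change detector with absolute
temperature gates can and cannot be trusted.
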