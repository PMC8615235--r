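---
title: "Geometric waveform features and automatic CTS electrodiagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric waveform features and automatic CTS electrodiagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Carpal tunnel syndrome (CTS) is a compression mononeuropathy of the median
nerve at the wrist; the ulnar nerve, which does not pass through the carpal
tunnel, is unaffected and serves as a within-hand control. Nerve conduction
studies (NCS) record evoked potentials — sensory nerve action potentials
(SNAPs, microvolts) and compound muscle action potentials (CMAPs,
millivolts) — whose latencies, amplitudes and conduction velocities grade
the severity of the neuropathy. This package implements the full analysis
chain for that problem: synthesis of realistic eight-channel per-hand
recordings, critical-point detection, extraction of a canonical set of
geometric waveform features, a four-grade severity rule, wrapper feature
selection, and leave-one-out cross-validated (LOOCV) classification.

## The eight-channel montage and the severity rule

Each hand is represented by eight channels (`channel_montage()`): median
sensory to digits 2 and 4, ulnar sensory to digits 4 and 5 (wrist-digit
distance 140 mm), and median/ulnar motor with distal (70 mm) and proximal
stimulation (elbow-wrist segment 230 mm). Severity uses a four-group
modification of the Bland neurophysiological scale (`ncs_grade()`), driven
by three measurements:

* the median digit-2 sensory conduction velocity CV = distance / onset
  latency (threshold 40 m/s),
* the median distal motor (take-off) latency DML (thresholds 4.5 and
  6.5 ms),
* whether the digit-2 SNAP is detectable at all.

Grade D (severe) requires an absent SNAP with DML at or above 4.5 ms, or
DML > 6.5 ms; grade C (moderate) a DML in 4.5–6.5 ms with a preserved SNAP;
grade B (mild) slowed or absent sensory conduction with DML < 4.5 ms;
grade A is normal. Published descriptions of these thresholds sometimes
carry a "m/s" unit on the latency values; latencies here are milliseconds,
the only physically sensible reading. The boundary DML of exactly 4.5 ms is
assigned to C (SNAP present) or D (SNAP absent), so the rule is exhaustive
and severity is monotone in DML. The 4-, 3- and 2-class problems coarsen
A/B/C/D to A/BC/D and A/BCD (`class_labels()`); clinical assessment
distinguishes three groups only, so no clinical 4-class problem exists.

## The synthetic generator and what it emulates

No public NCS waveform cohort exists at this granularity, so
`generate_cohort()` synthesises one. Each channel is an analytic biphasic
template — an asymmetric Gaussian positive lobe minus a delayed, broader
negative lobe (membrane repolarization) — plus sinusoidal isoelectric-line
drift and i.i.d. Gaussian noise. Default acquisition settings are typical
EMG-laboratory values: 0.05 ms sampling (20 kHz), 20 ms sensory and 50 ms
motor sweeps, with the stimulus at 2 ms (sensory) or 5 ms (motor) so a
pre-stimulus baseline segment exists.

Grade-conditional parameters (`default_grade_params()`) place the median
channels inside each grade's defining region: normal conduction for A;
sensory CV 28–40 m/s with preserved DML for B; DML 4.5–6.5 ms with a
preserved SNAP for C; DML above 6.5 ms (or above 4.5 ms with an absent
SNAP, half of the severe hands) for D. A `margin` argument shrinks these
intervals away from the thresholds symmetrically; amplitudes fall and the
pulse widths broaden with severity (axonal loss and temporal dispersion),
and sensory noise (0.8 µV default) exceeds motor noise (0.05 mV), as in
real recordings. Ulnar channels are drawn from normal distributions for
every grade. The default cohort sizes are 19/10/17/19 hands for grades
A/B/C/D — the 65-hand study design, 19 controls and 46 patients — and a
`disagreement_rate` moves that fraction of hands to an adjacent clinical
label, emulating the imperfect clinic-to-NCS correlation.

Two generator properties make the downstream stages testable:

* **Self-calibration.** The detector's onset lands a deterministic offset
  away from any nominal template take-off (the offset depends on the flank
  width and smoothing window). `generate_hand()` measures this offset once
  per pulse shape on the noiseless template and shifts the pulse so that
  the *measured* onset latency equals the drawn grade-conditional value.
  Consequently, at zero noise and positive margin, grading the extracted
  features returns the requested grade for every hand — by construction,
  not by tuning.
* **Absent SNAPs** are generated as sub-threshold stumps (0.2–1 µV against
  a 2 µV detection floor), so "no response" is a reachable, well-defined
  outcome of detection rather than a special code path.

What the generator does **not** emulate: polyphasic (multi-lobe)
potentials, stimulus artifacts, 50/60 Hz interference, temperature
effects, F-waves, and inter-hand correlation within a participant. Passing
tests therefore demonstrate correctness of the measurement chain on
clean-to-moderately-noisy biphasic morphologies, not clinical performance
on real recordings.

## Preprocessing and critical-point detection

`smooth_trace()` is a centred moving average (shrinking windows at the
edges); `detrend_trace()` subtracts the least-squares line fitted to the
baseline regions of the sweep (pre-stimulus segment plus the final tenth)
and re-zeroes to the pre-stimulus mean, annihilating linear drift exactly
while leaving the response untouched. Detection (`detect_critical_points()`)
runs on the smoothed signal — default windows 11 samples (sensory) and 5
(motor), the sensory channel being noisier — and projects the peak and
trough back to the raw-trace extremum within half a window, so noiseless
amplitudes are recovered exactly.

The peak is the post-stimulus maximum and the trough the minimum after it.
The onset is found by scanning backward from the peak until the local
slope falls below a threshold fraction (default 0.05, one common constant
for all signals) of the secant slope from the current sample to the peak;
the offset by the symmetric forward scan from the trough once the signal
has recovered halfway to baseline, capped at three rise-durations past the
trough. Two numerical choices matter:

* the local slope is a one-sided least-squares fit on the **raw** series
  over four smoothing windows (trailing for the onset, leading for the
  offset). i.i.d. noise averages out of an OLS slope at the n^(3/2) rate,
  whereas a slope fit on the already-smoothed series inherits its
  correlated noise; the one-sided orientation keeps the estimate from
  mixing the two flanks. The same span is used at every noise level, so
  detections on noisy and clean copies of a trace agree;
* the trigger must hold for two consecutive scan positions, and is blocked
  in the top 40% of the rise, which suppresses isolated noise dips.

Because the trigger compares a slope to a relative threshold, detected
indices are invariant to amplitude scaling and equivariant to time shifts.
At a signal-to-noise ratio of 10 (noise SD one tenth of the peak), onset
and peak reproduce their noiseless positions within ±3 samples in over 95%
of trials. The trough and offset cannot: the repolarization lobe is ~30%
of the peak amplitude and its extremum bowl varies by well under the noise
SD across ±5 samples, so any local estimator has irreducible jitter there
— the package tests those two points at ±8 samples. The offset is the
least sharply defined point of the four; features meant to be robust to
that (the regression slopes `fit_left`/`fit_right`, the half-maximum
duration) depend on it only weakly.

## The 34 trace features and the 302-entry hand vector

Per trace, eight common clinical measures — onset-to-peak height `H`, peak
height above baseline `Hmax`, peak-to-trough `Hmaxmin`, onset latency
`Lon`, peak latency `Lpeak`, rise time `Lonpeak`, conduction velocity
`CV`, positive-lobe area `A` — and 26 geometric ones: the expanded
absolute area `|Ae|` (absolute deviation from baseline, adding the
repolarization lobe), duration `D`, full duration at half maximum `Dh2`,
the four subareas `UL`/`LL`/`UR`/`LR` cut by the half-maximum line and the
vertical through the peak, their four sums, eleven area ratios and four
slopes (secant and regression, each flank). Three enumeration decisions
were genuinely open and are fixed as follows:

* "all possible ratios" between the derived areas is arithmetically
  inconsistent with a 34-feature total; the canonical registry keeps one
  ratio per geometrically distinct comparison (11 ratios), which closes
  the set at exactly 34. The registry (`feature_registry()`) is the single
  source of truth for names and order;
* the half-maximum level is measured from the baseline (`Hmax/2` above
  it), not from the onset voltage, matching how the subareas are drawn;
* subareas are defined on the positive lobe only; the negative lobe enters
  through `|Ae|`.

The per-hand vector (`hand_features()`) concatenates the 34 features for
the eight channels (272 entries, channel-major) and 30 median-minus-ulnar
difference features: for each homologous pair (sensory digit 4, motor
distal, motor proximal) the differences of Lon, Lpeak, CV, H, A, D, Dh2,
both secant slopes and `|Ae|` — 3 × 10 = 30, total 302. The motor-segment
CV (proximal trace) uses segment distance over the proximal-distal
latency difference; a nonpositive difference yields `NA`. Absent responses
set amplitude/area features to 0 and latency/CV/duration/slope features to
`NA`; degenerate ratio denominators (below 1e-12) also yield `NA`.

Integration is trapezoidal on the raw samples between the projected
critical points. The subarea partition is computed from pointwise-clipped
integrands whose identities (`(y-h/2)^+ + clip(y,0,h/2) = y^+`) make
`UL+LL+UR+LR = Left+Right = Upper+Lower = A` hold to floating-point
precision, not merely to a tolerance.

## Classification, tuning, selection, evaluation

Five deterministic classifiers are wrapped behind one interface
(`classifier_config()`): logistic regression (multinomial), SVM (linear
kernel for the 2-class problem, RBF with cost 0.9 otherwise — the tuned
values), kNN (5 neighbours; exact small-n implementation with
smallest-class tie-breaking, because randomized tie-breaks would make
LOOCV non-reproducible), a depth-capped decision tree, and Gaussian naive
Bayes (with a 1e-6 variance floor so that noiseless synthetic columns with
zero within-class variance keep finite densities). Features are
median-imputed and z-score standardised with training-fold statistics
inside every LOOCV fold — nothing from the held-out row leaks into
training. Single-feature parameter tuning (`tune_parameter()`) scores each
grid value by the number of features whose single-feature LOOCV accuracy
comes within 0.01 of that feature's best over the grid, ties to the
smallest value; tuning on the full table once (not nested in the outer
LOOCV) is the package default and carries the usual optimistic bias, which
is why the headline numbers come from synthetic cohorts whose ground truth
is known.

The custom selection (`hybrid_feature_selection()`) combines sequential
backward and forward passes around two wrappers (kNN and SVM). Phase 1
tentatively removes each feature in column order and drops it permanently
iff neither wrapper's accuracy falls; phase 2 re-adds the dropped features
in the same order, keeping those that strictly improve at least one
wrapper. The alternative literal reading — drop whenever removal improved
neither wrapper, even if it hurt — discards accuracy-critical features and
is available behind `literal = TRUE` for comparison only. The full
decision trace is logged and `replay_selection()` reproduces the final set
from it exactly.

`evaluate_all()` runs the 2/3/4-class problems against NCS grades and the
2/3-class problems against clinical labels, for the common, novel and
combined feature sets, and reports LOOCV accuracies plus confusion
matrices with per-row (recall) and per-column (precision) rates
(`confusion_and_rates()`). `run_pipeline()` ties the stages together and
writes a fully reproducible report bundle: a run is reconstructible from
its JSON manifest alone.

## Known limitations

* On noiseless cohorts the two grade-defining measurements separate
  patients from controls perfectly (LOOCV accuracy 1.0 for SVM and kNN on
  that two-column table). On the full 302-column table, kNN loses 0–8% of
  hands across seeds: roughly half of the columns belong to ulnar channels
  that are by design identically distributed for every grade, and their
  variation dilutes 5-NN distances. This is a property of unweighted
  nearest-neighbour classification in many-irrelevant-feature settings,
  and is exactly what the wrapper selection is for.
* With very small groups, LOOCV is structurally pessimistic: a held-out
  member of a 2-hand class leaves one same-class training row, which can
  never carry a 5-NN majority. Perfect-accuracy checks therefore use
  cohorts with enough hands per class.
* The generator emulates biphasic morphologies only; polyphasic
  decomposition and artifact rejection beyond drift removal are out of
  scope.

## Problem sizes used by the test suite

The suite and the acceptance script run 65-hand default cohorts for
grading and separation checks, 500 random pulses for the area-conservation
sweep, 200 seeded trials at SNR 10 for the detection-stability property,
40-row tables for selection (with an exhaustive 2^5 subset-search oracle)
and 20 label permutations of a 64-row table for the leakage guard; the
full run completes in well under two minutes on one core.
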